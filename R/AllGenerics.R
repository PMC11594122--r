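#' @rdname TractSet-class
#' @param x a \code{TractSet}.
#' @export
setGeneric("tractIds", function(x) standardGeneric("tractIds"))

#' @rdname TractSet-class
#' @export
setGeneric("tractNames", function(x) standardGeneric("tractNames"))

#' @rdname TractSet-class
#' @export
setGeneric("tractGeometry", function(x) standardGeneric("tractGeometry"))

#' @rdname TractSet-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname TractSet-class
#' @export
setGeneric("outcomeRates", function(x) standardGeneric("outcomeRates"))

#' @rdname TractSet-class
#' @export
setGeneric("outcomeRates<-", function(x, value) standardGeneric("outcomeRates<-"))

#' @rdname TractSet-class
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))

#' @rdname SyntheticTruth-class
#' @param x a \code{SyntheticTruth}.
#' @export
setGeneric("trueR2", function(x) standardGeneric("trueR2"))

#' @rdname ChipGrid-class
#' @param x a \code{ChipGrid}.
#' @export
setGeneric("chipIds", function(x) standardGeneric("chipIds"))
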