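# Chip-level visual feature extraction: per-band standardization and a
# pluggable extractor. The default surrogate computes interpretable per-band
# summary statistics and projects them to the working dimension with a seeded
# random linear map; a deep-CNN backend slot exists but is optional and not
# bundled.

#' ImageNet per-band standardization constants
#'
#' The published per-band means and standard deviations used to standardize
#' display-range RGB images before a pretrained convolutional network.
#' @export
imagenetStandardization <- list(mean = c(0.485, 0.456, 0.406),
                                sd = c(0.229, 0.224, 0.225))

#' Specification of a chip feature extractor
#'
#' @slot kind "surrogate" or "deep".
#' @slot D output dimension (default 2048, mirroring the penultimate-layer
#'   width of a 50-layer residual network).
#' @slot seed seed of the surrogate's random projection.
#' @slot mean,sd per-band standardization constants (sd > 0).
#' @export
setClass("ExtractorSpec", representation(
    kind = "character", D = "integer", seed = "integer",
    mean = "numeric", sd = "numeric"))

setValidity("ExtractorSpec", function(object) {
    msg <- character()
    if (!object@kind %in% c("surrogate", "deep"))
        msg <- c(msg, "kind must be 'surrogate' or 'deep'")
    if (any(object@sd <= 0)) msg <- c(msg, "standardization sd must be > 0")
    if (length(object@mean) != 3 || length(object@sd) != 3)
        msg <- c(msg, "need 3 per-band standardization constants")
    if (object@D < 69L)
        msg <- c(msg, "D must be at least the surrogate base feature count (69)")
    if (length(msg)) msg else TRUE
})

#' Create an extractor specification
#'
#' @param kind extractor backend; the surrogate is fully offline and
#'   deterministic, the deep backend requires an external pretrained network
#'   and is not bundled.
#' @param D feature dimension.
#' @param seed projection seed.
#' @param mean,sd per-band standardization constants; defaults are the
#'   published ImageNet values.
#' @return A validated \code{ExtractorSpec}.
#' @export
extractorSpec <- function(kind = c("surrogate", "deep"), D = 2048L,
                          seed = 0L, mean = imagenetStandardization$mean,
                          sd = imagenetStandardization$sd) {
    kind <- match.arg(kind)
    new("ExtractorSpec", kind = kind, D = as.integer(D),
        seed = as.integer(seed), mean = as.numeric(mean), sd = as.numeric(sd))
}

setMethod("show", "ExtractorSpec", function(object) {
    cat(sprintf("ExtractorSpec: %s, D = %d, seed = %d\n", object@kind,
                object@D, object@seed))
})

#' Standardize a chip band-wise
#'
#' Maps band b to \code{(v - mean_b) / sd_b}. Values are expected in [0, 1];
#' the standardization constants are applied to those unit-range values
#' directly.
#'
#' @param chip a [Chip-class] or a rows x cols x 3 array in [0, 1].
#' @param spec an \code{ExtractorSpec}.
#' @return A rows x cols x 3 standardized array.
#' @export
standardizeChip <- function(chip, spec = extractorSpec()) {
    px <- if (is(chip, "Chip")) chip@pixels else chip
    d <- dim(px)
    if (length(d) != 3 || d[3] != length(spec@mean))
        stop("band count (", d[3], ") does not match the spec's ",
             length(spec@mean), " standardization constants")
    out <- px
    for (b in seq_len(d[3]))
        out[, , b] <- (px[, , b] - spec@mean[b]) / spec@sd[b]
    out
}

## 23 summary statistics of one band: mean, sd, skewness, min, max,
## mean and sd of gradient magnitude, and 16 block means on a 4 x 4 grid.
bandBaseFeatures <- function(v) {
    nr <- nrow(v); nc <- ncol(v)
    gx <- v[, -1, drop = FALSE] - v[, -nc, drop = FALSE]
    gy <- v[-1, , drop = FALSE] - v[-nr, , drop = FALSE]
    mag <- sqrt(gx[-nr, , drop = FALSE]^2 + gy[, -nc, drop = FALSE]^2)
    ri <- ceiling(4 * seq_len(nr) / nr)
    ci <- ceiling(4 * seq_len(nc) / nc)
    sums <- rowsum(t(rowsum(v, ri)), ci)            # 4 x 4 block sums
    counts <- tabulate(ri, 4) %o% tabulate(ci, 4)
    blocks <- as.vector(t(sums) / counts)
    c(mean(v), stats::sd(v), e1071::skewness(v), min(v), max(v),
      mean(mag), stats::sd(mag), blocks)
}

## seeded D x 69 Gaussian projection, scaled by 1/sqrt(69)
surrogateProjection <- function(D, seed) {
    withSeed(seed, matrix(stats::rnorm(D * 69L), D, 69L) / sqrt(69))
}

#' Surrogate visual features of a chip
#'
#' Computes 23 interpretable statistics per band (mean, standard deviation,
#' skewness, min, max, mean and standard deviation of the gradient magnitude,
#' and 16 block means on a 4 x 4 grid; 69 in total) and applies a seeded
#' fixed random linear projection from 69 to D dimensions. Deterministic for
#' a fixed seed; almost surely injective on the 69-dimensional base.
#'
#' @param pixels rows x cols x 3 numeric array (already standardized by the
#'   caller when used through [extractFeatures()]).
#' @param D output dimension (>= 69).
#' @param seed projection seed.
#' @param projection optional precomputed projection matrix (D x 69) to avoid
#'   regenerating it per chip.
#' @return Numeric vector of length D.
#' @export
surrogateFeatures <- function(pixels, D = 2048L, seed = 0L,
                              projection = NULL) {
    stopifnot(length(dim(pixels)) == 3)
    base <- unlist(lapply(seq_len(dim(pixels)[3]),
                          function(b) bandBaseFeatures(pixels[, , b])))
    base[is.na(base)] <- 0           # skewness of a constant band
    if (is.null(projection)) projection <- surrogateProjection(D, seed)
    drop(projection %*% base)
}

#' Extract the feature vector of one chip
#'
#' Standardizes the chip per the spec, then dispatches to the configured
#' backend. A pure function of (pixels, spec): identical chips yield
#' bit-identical vectors.
#'
#' @param chip a [Chip-class].
#' @param spec an \code{ExtractorSpec}.
#' @param projection optional precomputed surrogate projection.
#' @return Numeric feature vector of length \code{spec@D}.
#' @export
extractFeatures <- function(chip, spec = extractorSpec(),
                            projection = NULL) {
    std <- standardizeChip(chip, spec)
    switch(spec@kind,
        surrogate = surrogateFeatures(std, spec@D, spec@seed, projection),
        deep = stop("the deep extractor backend (pretrained 50-layer ",
                    "residual network) is not available in this ",
                    "installation; fall back to the surrogate extractor: ",
                    "extractorSpec(kind = 'surrogate')"))
}

#' Feature matrix of a chip collection
#'
#' @param chips named list of [Chip-class] objects.
#' @param spec an \code{ExtractorSpec}.
#' @return A \code{D x n_chips} matrix with chip ids as column names.
#' @export
chipFeatureMatrix <- function(chips, spec = extractorSpec()) {
    proj <- if (spec@kind == "surrogate")
        surrogateProjection(spec@D, spec@seed) else NULL
    out <- vapply(chips, function(ch) extractFeatures(ch, spec, proj),
                  numeric(spec@D))
    dim(out) <- c(spec@D, length(chips))
    colnames(out) <- vapply(chips, function(ch) ch@chipId, character(1))
    rownames(out) <- sprintf("f%04d", seq_len(spec@D) - 1L)
    out
}
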