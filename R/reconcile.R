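# Identifier reconciliation between tract geography and outcome layers:
# subdivision-zeroing of ids, dissolving subdivided tracts, population-
# weighted outcome merging, matching of joined layers, and boundary
# simplification.

#' Normalize a tract identifier to its base (subdivision digits zeroed)
#'
#' Handles the two identifier dialects found in tract data: decimal tract
#' names of the form "XXXX.YY" (four digits, a dot, two subdivision digits)
#' and all-digit GEOIDs whose last two digits encode the subdivision. In both
#' cases the two trailing subdivision digits are replaced by "00". The
#' operation is idempotent and vectorized.
#'
#' @param id character vector of tract names or GEOIDs.
#' @return Character vector of base identifiers.
#' @examples
#' normalizeId(c("1201.05", "0740.00", "29510124612"))
#' @export
normalizeId <- function(id) {
    id <- as.character(id)
    isName <- grepl("^[0-9]{4}\\.[0-9]{2}$", id)
    isGeoid <- grepl("^[0-9]{3,}$", id)
    bad <- !isName & !isGeoid
    if (any(bad))
        stop("malformed tract id(s): ", paste(utils::head(id[bad], 5),
             collapse = ", "),
             " -- expected the \"XXXX.YY\" name dialect or an all-digit GEOID")
    out <- id
    out[isName] <- paste0(substr(id[isName], 1, 5), "00")
    out[isGeoid] <- paste0(substr(id[isGeoid], 1, nchar(id[isGeoid]) - 2), "00")
    out
}

#' Merge member outcome rates by population weighting
#'
#' The joined-area rate is the population-weighted mean of its members'
#' rates, \eqn{\bar w = \sum_i w_i x_i / \sum_i w_i}, with \eqn{w_i} the
#' member population and \eqn{x_i} its rate.
#'
#' @param population numeric member populations (weights).
#' @param rate numeric member rates (%).
#' @return The merged rate, always within the member rate range.
#' @examples
#' mergeOutcomes(c(100, 300), c(30, 40))  # 37.5
#' @export
mergeOutcomes <- function(population, rate) {
    stopifnot(length(population) == length(rate), length(rate) >= 1)
    if (anyNA(rate))
        stop("missing outcome rate for member(s) ",
             paste(which(is.na(rate)), collapse = ", "),
             "; merge aborted")
    if (anyNA(population) || any(population < 0))
        stop("member populations must be non-negative")
    if (sum(population) == 0)
        stop("zero total population: weight mass is zero")
    sum(population * rate) / sum(population)
}

#' Dissolve a tract layer to one record per base identifier
#'
#' Groups records by their normalized base id ([normalizeId()]), unions the
#' member polygons (as multi-part geometries; census subdivisions are
#' interior-disjoint, so the collection is the union), sums populations and
#' merges outcome rates by [mergeOutcomes()] where present.
#'
#' @param tracts a [TractSet-class]; ids are taken from tract names where
#'   present, else from tract ids.
#' @param by which identifier to normalize: "auto" (names if all present,
#'   else ids), "name" or "id".
#' @return A [TractSet-class] with one record per distinct base id;
#'   \code{nMembers} counts merged members.
#' @export
dissolveByBase <- function(tracts, by = c("auto", "name", "id")) {
    by <- match.arg(by)
    if (length(tracts) == 0) return(tracts)
    nm <- tractNames(tracts)
    useName <- switch(by, name = TRUE, id = FALSE, auto = all(!is.na(nm)))
    raw <- if (useName) nm else tractIds(tracts)
    base <- normalizeId(raw)
    groups <- split(seq_along(base), base)
    ids <- names(groups)
    geom <- vector("list", length(groups))
    pop <- numeric(length(groups))
    rate <- rep(NA_real_, length(groups))
    nmem <- integer(length(groups))
    g <- tractGeometry(tracts)
    for (i in seq_along(groups)) {
        idx <- groups[[i]]
        geom[[i]] <- do.call(c, g[idx])          # multi-part union
        pop[i] <- sum(populations(tracts)[idx])
        r <- outcomeRates(tracts)[idx]
        if (all(!is.na(r)))
            rate[i] <- mergeOutcomes(populations(tracts)[idx], r)
        nmem[i] <- length(idx)
    }
    TractSet(tractId = ids, geometry = geom, population = pop,
             outcomeRate = rate,
             tractName = if (useName) ids else rep(NA_character_, length(ids)),
             nMembers = nmem, crs = tracts@crs)
}

#' Match two joined identifier sets
#'
#' Intersects the base-id sets of two layers (e.g., the dissolved geometry
#' layer and the dissolved outcome layer) and reports the unmatched ids on
#' each side, so the join bookkeeping is auditable.
#'
#' @param idsA,idsB character vectors of normalized base ids.
#' @param quiet suppress the count message.
#' @return A list: \code{matched} (sorted intersection), \code{unmatchedA},
#'   \code{unmatchedB}.
#' @export
matchJoinedSets <- function(idsA, idsB, quiet = FALSE) {
    a <- unique(idsA); b <- unique(idsB)
    matched <- sort(intersect(a, b))
    res <- list(matched = matched,
                unmatchedA = sort(setdiff(a, b)),
                unmatchedB = sort(setdiff(b, a)))
    if (!quiet)
        message(length(matched), " matched; ", length(res$unmatchedA),
                " unmatched in layer A; ", length(res$unmatchedB),
                " unmatched in layer B")
    res
}

#' Simplify a polygon boundary (Douglas-Peucker)
#'
#' Recursive polyline simplification of each ring at a distance tolerance.
#' Vertex count is non-increasing in the tolerance; a tolerance of 0 returns
#' the input unchanged; rings stay closed.
#'
#' @param geom a geometry (list of parts of rings) or a bare ring matrix.
#' @param tolerance distance tolerance (map units), >= 0.
#' @return Simplified geometry of the same structure as the input.
#' @export
simplifyBoundary <- function(geom, tolerance) {
    stopifnot(tolerance >= 0)
    if (is.matrix(geom)) {
        if (nrow(geom) < 4)
            stop("degenerate ring: need at least 4 vertices")
        return(dpRing(geom, tolerance))
    }
    lapply(geom, function(part) lapply(part, function(ring) {
        if (nrow(ring) < 4)
            stop("degenerate ring: need at least 4 vertices")
        dpRing(ring, tolerance)
    }))
}

#' Search the simplification tolerance for a maximum vertex count
#'
#' Douglas-Peucker is tolerance-parameterized; when a target vertex count is
#' required instead (e.g., a compact search-query geometry of at most 54
#' vertices), this helper bisects the tolerance until the simplified ring has
#' at most \code{maxVertices}.
#'
#' @param ring an n x 2 ring matrix.
#' @param maxVertices maximum vertices allowed (>= 3).
#' @param maxIter bisection iterations.
#' @return A list: \code{ring} (simplified), \code{tolerance} (the tolerance
#'   found).
#' @export
simplifyToVertexCount <- function(ring, maxVertices, maxIter = 60) {
    stopifnot(maxVertices >= 3)
    if (nrow(ring) <= maxVertices)
        return(list(ring = ring, tolerance = 0))
    bb <- geometryBBox(ringGeometry(ring))
    lo <- 0
    hi <- max(bb[3] - bb[1], bb[4] - bb[2])
    ans <- dpRing(ring, hi)
    tol <- hi
    for (i in seq_len(maxIter)) {
        mid <- (lo + hi) / 2
        cand <- dpRing(ring, mid)
        if (nrow(cand) <= maxVertices) {
            hi <- mid; ans <- cand; tol <- mid
        } else lo <- mid
    }
    list(ring = ans, tolerance = tol)
}
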