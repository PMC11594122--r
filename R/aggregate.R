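# Chip-tract intersection weights (pixel counting) and the two weighted
# aggregations they drive: tract-level mean feature vectors and chip-level
# outcome rates.

#' Pixel-count intersection weights between chip windows and tracts
#'
#' A pixel belongs to a tract iff its centre point lies inside the tract
#' polygon (boundary inclusive); centres on a shared boundary are assigned to
#' the tract with the lexicographically smallest id. Zero-count pairs are
#' omitted.
#'
#' @param grid a [ChipGrid-class].
#' @param tracts a [TractSet-class] in the same coordinate system as the
#'   grid.
#' @param i window indices (default: all windows).
#' @return data.frame with columns \code{chip_id}, \code{tract_id},
#'   \code{pixel_count}.
#' @export
pixelWeights <- function(grid, tracts, i = seq_len(length(grid))) {
    if (!identical(grid@crs, tracts@crs))
        stop("coordinate-system mismatch: grid is '", grid@crs,
             "', tracts are '", tracts@crs,
             "'; reproject the tracts into the raster CRS first")
    cs <- grid@chipSize
    ids <- chipIds(grid)
    res <- vector("list", length(i))
    for (k in seq_along(i)) {
        w <- i[k]
        tr <- chipTransform(grid, w)
        li <- labelPixels(cs, cs, tr, tracts)
        counts <- tabulate(li$label, nbins = length(li$ids))
        nz <- which(counts > 0)
        if (length(nz))
            res[[k]] <- data.frame(chip_id = ids[w], tract_id = li$ids[nz],
                                   pixel_count = counts[nz],
                                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(chip_id = character(), tract_id = character(),
                          pixel_count = integer(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Filter chips to the usable subset
#'
#' A chip is kept iff (a) its footprint rectangle is geometrically covered by
#' the region boundary polygon and (b) it intersects at least one tract
#' (i.e., it has at least one pixel-count weight).
#'
#' @param grid a [ChipGrid-class].
#' @param boundary the region boundary geometry.
#' @param weights data.frame from [pixelWeights()].
#' @return The subset [ChipGrid-class] of usable windows.
#' @export
filterUsableChips <- function(grid, boundary, weights) {
    cs <- grid@chipSize
    ids <- chipIds(grid)
    keep <- logical(length(grid))
    for (w in seq_len(length(grid))) {
        tr <- chipTransform(grid, w)
        xs <- tr[3] + tr[1] * c(0, cs) + tr[2] * c(0, cs)
        ys <- tr[6] + tr[4] * c(0, cs) + tr[5] * c(0, cs)
        covered <- rectCoveredByGeometry(min(xs), min(ys), max(xs), max(ys),
                                         boundary)
        keep[w] <- covered && ids[w] %in% weights$chip_id
    }
    grid[which(keep)]
}

#' Pixel-weighted mean feature vector of one tract
#'
#' Component-wise weighted mean of the chip feature vectors intersecting the
#' tract, weighted by the number of chip pixels inside it.
#'
#' @param features \code{D x n_chips} matrix (chip ids as column names).
#' @param weights data.frame of [pixelWeights()] rows for this tract.
#' @return A list: \code{values} (numeric D), \code{totalWeight},
#'   \code{nChips}.
#' @export
tractFeature <- function(features, weights) {
    if (nrow(weights) == 0 || sum(weights$pixel_count) <= 0)
        stop("zero total pixel weight for tract")
    miss <- setdiff(weights$chip_id, colnames(features))
    if (length(miss))
        stop("missing chip feature vector(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    w <- weights$pixel_count
    F <- features[, weights$chip_id, drop = FALSE]
    list(values = drop(F %*% w) / sum(w), totalWeight = sum(w),
         nChips = nrow(weights))
}

#' Pixel-weighted outcome rate of one chip
#'
#' The chip rate is the mean of the intersecting tracts' outcome rates
#' weighted by the number of chip pixels falling in each tract.
#'
#' @param tracts a [TractSet-class] with outcome rates.
#' @param weights data.frame of [pixelWeights()] rows for this chip.
#' @return A list: \code{rate}, \code{nTracts}.
#' @export
chipOutcome <- function(tracts, weights) {
    if (nrow(weights) == 0 || sum(weights$pixel_count) <= 0)
        stop("zero pixel weight mass for chip")
    rates <- outcomeRates(tracts)[match(weights$tract_id, tractIds(tracts))]
    if (anyNA(rates))
        stop("missing outcome rate for tract(s) ",
             paste(weights$tract_id[is.na(rates)], collapse = ", "))
    list(rate = sum(weights$pixel_count * rates) / sum(weights$pixel_count),
         nTracts = nrow(weights))
}

#' Aggregate chip features to all tracts
#'
#' @param features \code{D x n_chips} matrix.
#' @param weights data.frame from [pixelWeights()] (usable chips only).
#' @return A list: \code{values} (D x n_tracts matrix, tract ids as column
#'   names, sorted), \code{totalWeight}, \code{nChips} (named vectors).
#' @export
tractFeatureMatrix <- function(features, weights) {
    split_w <- split(weights, weights$tract_id)
    ids <- sort(names(split_w))
    vals <- vapply(ids, function(id) tractFeature(features, split_w[[id]])$values,
                   numeric(nrow(features)))
    dim(vals) <- c(nrow(features), length(ids))
    dimnames(vals) <- list(rownames(features), ids)
    list(values = vals,
         totalWeight = vapply(split_w[ids], function(w) sum(w$pixel_count),
                              numeric(1)),
         nChips = vapply(split_w[ids], nrow, integer(1)))
}

#' Assemble the tract design matrix
#'
#' Joins tract-level mean feature vectors with tract outcome rates into a
#' \code{SummarizedExperiment} (features as the assay, tracts as columns,
#' outcome and aggregation bookkeeping in \code{colData}). Columns are
#' ordered by tract id; tracts lacking features or outcomes are excluded and
#' reported via a message.
#'
#' @param tractFeatures result of [tractFeatureMatrix()].
#' @param tracts a [TractSet-class] carrying outcome rates.
#' @return A \code{SummarizedExperiment}; the excluded tract ids are kept in
#'   \code{metadata(se)$excluded}.
#' @export
buildDesignMatrix <- function(tractFeatures, tracts) {
    fids <- colnames(tractFeatures$values)
    oids <- tractIds(tracts)[!is.na(outcomeRates(tracts))]
    ids <- sort(intersect(fids, oids))
    if (length(ids) == 0)
        stop("no tract has both a feature vector and an outcome rate")
    excluded <- sort(setdiff(union(fids, oids), ids))
    if (length(excluded))
        message("excluding ", length(excluded),
                " tract(s) lacking features or outcomes: ",
                paste(utils::head(excluded, 5), collapse = ", "))
    rates <- outcomeRates(tracts)[match(ids, tractIds(tracts))]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = tractFeatures$values[, ids, drop = FALSE]),
        colData = S4Vectors::DataFrame(
            tract_id = ids,
            outcome_rate = rates,
            total_weight = tractFeatures$totalWeight[ids],
            n_chips = tractFeatures$nChips[ids],
            row.names = ids))
    S4Vectors::metadata(se)$excluded <- excluded
    se
}

#' Extract the regression inputs from a design matrix
#'
#' @param se a \code{SummarizedExperiment} from [buildDesignMatrix()].
#' @return A list: \code{X} (n x D matrix, tracts as rows), \code{y}
#'   (outcome rates), \code{ids}.
#' @export
designInputs <- function(se) {
    list(X = t(SummarizedExperiment::assay(se, "features")),
         y = se$outcome_rate,
         ids = colnames(se))
}
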