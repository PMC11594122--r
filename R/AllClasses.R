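#' @include AllGenerics.R
#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib tractscape, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# SyntheticConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic study-region generator
#'
#' Holds every knob of the synthetic data generator: the random seed, the
#' number of census tracts, the planar extent (1 map unit = 1 m), the raster
#' pixel size, the number K of smooth latent fields, their correlation length,
#' the outcome model (\code{outcomeBase + sum(beta * tract-mean latent) +
#' Normal(0, noiseSd^2)} in percentage points), the tract population range,
#' the per-pixel rendering noise and the raw integer ceiling of rendered
#' rasters. Identical configurations yield bit-identical outputs everywhere.
#'
#' @slot seed integer random seed.
#' @slot nTracts number of tracts (>= 2).
#' @slot extent numeric(4) bounding box \code{c(xmin, ymin, xmax, ymax)} in m.
#' @slot pixelSize raster pixel edge in m (default 10, the Sentinel-2 10 m
#'   visual-band resolution the pipeline targets).
#' @slot nLatent number K of latent fields (>= 1).
#' @slot fieldLengthScale Gaussian blur length of the latent fields, in m.
#' @slot beta numeric(K) outcome coefficients (percentage points per latent
#'   unit).
#' @slot noiseSd tract-level outcome noise standard deviation (percentage
#'   points).
#' @slot outcomeBase mean outcome rate (%).
#' @slot populationRange integer range (min, max) for uniform tract
#'   populations.
#' @slot pixelNoiseSd per-pixel rendering noise, as a fraction of the unit
#'   field standard deviation.
#' @slot rawMax raw integer ceiling of rendered raster bands (the
#'   normalisation divisor downstream, default 10000).
#' @seealso [syntheticConfig()], [generateRegion()], [generateLatentFields()]
#' @export
setClass("SyntheticConfig", representation(
    seed = "integer", nTracts = "integer", extent = "numeric",
    pixelSize = "numeric", nLatent = "integer", fieldLengthScale = "numeric",
    beta = "numeric", noiseSd = "numeric", outcomeBase = "numeric",
    populationRange = "numeric", pixelNoiseSd = "numeric", rawMax = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nTracts < 2L) msg <- c(msg, "nTracts must be >= 2")
    if (object@nLatent < 1L) msg <- c(msg, "nLatent must be >= 1")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (length(object@extent) != 4 || object@extent[3] <= object@extent[1] ||
        object@extent[4] <= object@extent[2])
        msg <- c(msg, "extent must be c(xmin, ymin, xmax, ymax) with positive span")
    if (length(object@beta) != object@nLatent)
        msg <- c(msg, "beta must have nLatent coefficients")
    if (length(object@populationRange) != 2 ||
        object@populationRange[1] > object@populationRange[2] ||
        object@populationRange[1] < 0)
        msg <- c(msg, "populationRange must be non-negative c(min, max)")
    if (object@pixelNoiseSd < 0) msg <- c(msg, "pixelNoiseSd must be >= 0")
    if (object@rawMax <= 0) msg <- c(msg, "rawMax must be > 0")
    if (object@fieldLengthScale <= 0)
        msg <- c(msg, "fieldLengthScale must be > 0")
    if (length(msg)) msg else TRUE
})

#' Create a synthetic-generator configuration
#'
#' Defaults describe the study conditions the generator emulates: 250 tracts
#' of widely varying size over a 11.2 km square (10 m pixels, a 5 x 5 grid of
#' 224 x 224-pixel chips), K = 6 latent fields with an 800 m correlation
#' length, an outcome centred at 39.2% (the median crude obesity prevalence of
#' the real tract data the pipeline targets) with tract noise of 3.5
#' percentage points.
#'
#' @param seed integer seed; every generator output is a pure function of the
#'   configuration.
#' @param nTracts,extent,pixelSize,nLatent,fieldLengthScale,beta,noiseSd,outcomeBase,populationRange,pixelNoiseSd,rawMax
#'   see the class slots.
#' @return A validated \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, nTracts = 4, extent = c(0, 0, 2240, 2240))
#' @export
syntheticConfig <- function(seed = 1L, nTracts = 250L,
                            extent = c(0, 0, 11200, 11200),
                            pixelSize = 10, nLatent = 6L,
                            fieldLengthScale = 800,
                            beta = c(4, 3, 2, 2, 1, 1)[seq_len(nLatent)],
                            noiseSd = 3.5, outcomeBase = 39.2,
                            populationRange = c(102, 75569),
                            pixelNoiseSd = 0.1, rawMax = 10000) {
    new("SyntheticConfig", seed = as.integer(seed),
        nTracts = as.integer(nTracts), extent = as.numeric(extent),
        pixelSize = pixelSize, nLatent = as.integer(nLatent),
        beta = as.numeric(beta), fieldLengthScale = fieldLengthScale,
        noiseSd = noiseSd, outcomeBase = outcomeBase,
        populationRange = as.numeric(populationRange),
        pixelNoiseSd = pixelNoiseSd, rawMax = rawMax)
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig: seed", object@seed, "|", object@nTracts, "tracts |",
        object@nLatent, "latent fields\n")
    cat("  extent", paste(object@extent, collapse = ", "), "(m), pixel",
        object@pixelSize, "m\n")
    cat("  outcome =", object@outcomeBase, "+ beta.z + N(0,",
        object@noiseSd, "^2) %\n")
})

# ---------------------------------------------------------------------------
# SyntheticTruth
# ---------------------------------------------------------------------------

#' Ground truth of a synthetic outcome draw
#'
#' Records the realised latent tract means, the realised across-tract signal
#' and noise variances and the resulting explainable variance fraction
#' \code{trueR2 = signal / (signal + noise)} — the quantity an ideal
#' imagery-based regressor could attain out of sample.
#'
#' @slot latentMeans n x K matrix of per-tract latent-field means.
#' @slot signalVariance realised variance of the linear signal across tracts.
#' @slot noiseVariance realised variance of the tract noise draw.
#' @slot trueR2 \code{signalVariance / (signalVariance + noiseVariance)}.
#' @export
setClass("SyntheticTruth", representation(
    latentMeans = "matrix", signalVariance = "numeric",
    noiseVariance = "numeric", trueR2 = "numeric"))

setValidity("SyntheticTruth", function(object) {
    if (object@trueR2 < 0 || object@trueR2 > 1)
        "trueR2 must lie in [0, 1]" else TRUE
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("trueR2", "SyntheticTruth", function(x) x@trueR2)

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@latentMeans), "tracts,",
        ncol(object@latentMeans), "latent fields\n")
    cat(sprintf("  signal var %.3f | noise var %.3f | true R2 %.3f\n",
                object@signalVariance, object@noiseVariance, object@trueR2))
})

# ---------------------------------------------------------------------------
# TractSet
# ---------------------------------------------------------------------------

#' A set of census tracts (or joined tracts)
#'
#' Tract records carry an identifier (an all-digit GEOID or a decimal
#' "XXXX.YY" tract name), a (multi)polygon geometry in one planar CRS, a
#' population count and an outcome rate in percent (possibly missing).
#' Joined sets produced by [dissolveByBase()] additionally count the members
#' merged into each base identifier.
#'
#' @slot tractId character identifiers, unique and non-empty.
#' @slot tractName optional "XXXX.YY" display names (NA when absent).
#' @slot geometry list of geometries (list of parts, each a list of rings).
#' @slot population numeric non-negative populations.
#' @slot outcomeRate numeric rates in [0, 100], NA when missing.
#' @slot nMembers integer count of original records per entry (1 for raw
#'   layers).
#' @slot crs coordinate-system tag shared by all geometries.
#' @seealso [dissolveByBase()], [generateRegion()]
#' @export
setClass("TractSet", representation(
    tractId = "character", tractName = "character", geometry = "list",
    population = "numeric", outcomeRate = "numeric", nMembers = "integer",
    crs = "character"))

setValidity("TractSet", function(object) {
    n <- length(object@tractId)
    msg <- character()
    if (any(!nzchar(object@tractId)) || anyNA(object@tractId))
        msg <- c(msg, "tract ids must be non-empty")
    if (anyDuplicated(object@tractId))
        msg <- c(msg, "tract ids must be unique")
    if (length(object@geometry) != n || length(object@population) != n ||
        length(object@outcomeRate) != n || length(object@tractName) != n ||
        length(object@nMembers) != n)
        msg <- c(msg, "slot lengths differ")
    if (any(object@population < 0, na.rm = TRUE))
        msg <- c(msg, "population must be >= 0")
    bad <- !is.na(object@outcomeRate) &
        (object@outcomeRate < 0 | object@outcomeRate > 100)
    if (any(bad)) msg <- c(msg, "outcome rates must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Construct a TractSet
#'
#' @param tractId character identifiers.
#' @param geometry list of geometries, one per tract.
#' @param population numeric populations.
#' @param outcomeRate numeric rates (%), NA allowed.
#' @param tractName optional display names.
#' @param nMembers member counts (default 1).
#' @param crs coordinate-system tag.
#' @return A validated \code{TractSet}.
#' @export
TractSet <- function(tractId, geometry, population,
                     outcomeRate = rep(NA_real_, length(tractId)),
                     tractName = rep(NA_character_, length(tractId)),
                     nMembers = rep(1L, length(tractId)),
                     crs = "synthetic:planar") {
    new("TractSet", tractId = as.character(tractId), geometry = geometry,
        population = as.numeric(population),
        outcomeRate = as.numeric(outcomeRate),
        tractName = as.character(tractName), nMembers = as.integer(nMembers),
        crs = crs)
}

#' @rdname TractSet-class
#' @export
setMethod("tractIds", "TractSet", function(x) x@tractId)
#' @rdname TractSet-class
#' @export
setMethod("tractNames", "TractSet", function(x) x@tractName)
#' @rdname TractSet-class
#' @export
setMethod("tractGeometry", "TractSet", function(x) x@geometry)
#' @rdname TractSet-class
#' @export
setMethod("populations", "TractSet", function(x) x@population)
#' @rdname TractSet-class
#' @export
setMethod("outcomeRates", "TractSet", function(x) x@outcomeRate)
#' @rdname TractSet-class
#' @param value replacement outcome rates (%).
#' @export
setReplaceMethod("outcomeRates", "TractSet", function(x, value) {
    x@outcomeRate <- as.numeric(value)
    validObject(x)
    x
})
#' @rdname TractSet-class
#' @export
setMethod("nMembers", "TractSet", function(x) x@nMembers)

#' @rdname TractSet-class
#' @export
setMethod("length", "TractSet", function(x) length(x@tractId))

#' @rdname TractSet-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TractSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@tractId)
    initialize(x, tractId = x@tractId[i], geometry = x@geometry[i],
               population = x@population[i], outcomeRate = x@outcomeRate[i],
               tractName = x@tractName[i], nMembers = x@nMembers[i])
})

setMethod("show", "TractSet", function(object) {
    cat("TractSet with", length(object), "tracts [crs:", object@crs, "]\n")
    r <- object@outcomeRate
    if (any(!is.na(r)))
        cat(sprintf("  outcome rate: %.1f-%.1f%% (%d missing)\n",
                    min(r, na.rm = TRUE), max(r, na.rm = TRUE), sum(is.na(r))))
    cat(sprintf("  total population: %s; joined members: %d\n",
                format(sum(object@population), big.mark = ","),
                sum(object@nMembers)))
})

#' @rdname TractSet-class
#' @export
setMethod("as.data.frame", "TractSet", function(x) {
    data.frame(tract_id = x@tractId, tract_name = x@tractName,
               population = x@population, outcome_rate = x@outcomeRate,
               n_members = x@nMembers,
               area = vapply(x@geometry, geometryArea, numeric(1)),
               stringsAsFactors = FALSE)
})

# ---------------------------------------------------------------------------
# GeoRaster
# ---------------------------------------------------------------------------

#' A georeferenced multi-band raster held in memory
#'
#' Pixel values are stored as a \code{nrow x ncol x nbands} numeric array
#' (raw integer counts for rendered synthetic imagery). The affine transform
#' follows the 6-coefficient convention \code{c(a, b, c, d, e, f)} mapping the
#' 0-based pixel-corner coordinates to map coordinates:
#' \code{x = c + a*col + b*row}, \code{y = f + d*col + e*row}; a north-up
#' raster has \code{b = d = 0}, \code{a = pixelSize}, \code{e = -pixelSize}.
#'
#' @slot values numeric array (rows x cols x bands).
#' @slot transform numeric(6) affine coefficients.
#' @slot crs coordinate-system tag.
#' @slot imageId identifier used in chip ids.
#' @export
setClass("GeoRaster", representation(
    values = "array", transform = "numeric", crs = "character",
    imageId = "character"))

setValidity("GeoRaster", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3)
        msg <- c(msg, "values must be a rows x cols x bands array")
    if (length(object@transform) != 6)
        msg <- c(msg, "transform needs 6 affine coefficients")
    if (length(msg)) msg else TRUE
})

#' @rdname GeoRaster-class
#' @param values,transform,crs,imageId see slots.
#' @export
GeoRaster <- function(values, transform, crs = "synthetic:planar",
                      imageId = "raster") {
    new("GeoRaster", values = values, transform = as.numeric(transform),
        crs = crs, imageId = imageId)
}

#' @rdname GeoRaster-class
#' @param x a \code{GeoRaster}.
#' @export
setMethod("dim", "GeoRaster", function(x) dim(x@values))

setMethod("show", "GeoRaster", function(object) {
    d <- dim(object@values)
    cat(sprintf("GeoRaster '%s': %d x %d px, %d band(s), pixel %g m [crs: %s]\n",
                object@imageId, d[1], d[2], d[3], object@transform[1],
                object@crs))
})

# ---------------------------------------------------------------------------
# ChipGrid
# ---------------------------------------------------------------------------

#' A grid of fixed-size chip windows over one raster
#'
#' Windows use 0-based, half-open pixel conventions; every window is exactly
#' \code{chipSize} pixels square and lies inside the parent image (ragged
#' edges are clamped inward, so last-row/column windows may overlap their
#' neighbours). Produced by [planChipGrid()].
#'
#' @slot imageId parent image identifier.
#' @slot rowIndex,colIndex 0-based grid coordinates of each window.
#' @slot rowOff,colOff 0-based pixel offsets of each window.
#' @slot chipSize window edge in pixels.
#' @slot imageDim integer(2) parent image (rows, cols).
#' @slot transform parent image affine (6 coefficients).
#' @slot crs coordinate-system tag.
#' @export
setClass("ChipGrid", representation(
    imageId = "character", rowIndex = "integer", colIndex = "integer",
    rowOff = "integer", colOff = "integer", chipSize = "integer",
    imageDim = "integer", transform = "numeric", crs = "character"))

setValidity("ChipGrid", function(object) {
    msg <- character()
    n <- length(object@rowIndex)
    if (length(object@colIndex) != n || length(object@rowOff) != n ||
        length(object@colOff) != n)
        msg <- c(msg, "window vectors differ in length")
    cs <- object@chipSize
    if (any(object@rowOff < 0L) || any(object@colOff < 0L) ||
        any(object@rowOff + cs > object@imageDim[1]) ||
        any(object@colOff + cs > object@imageDim[2]))
        msg <- c(msg, "windows must lie inside the parent image")
    if (length(msg)) msg else TRUE
})

#' @rdname ChipGrid-class
#' @export
setMethod("length", "ChipGrid", function(x) length(x@rowIndex))

#' @rdname ChipGrid-class
#' @export
setMethod("chipIds", "ChipGrid", function(x)
    sprintf("%s_%03d_%03d", x@imageId, x@rowIndex, x@colIndex))

#' @rdname ChipGrid-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ChipGrid", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, chipIds(x))
    initialize(x, rowIndex = x@rowIndex[i], colIndex = x@colIndex[i],
               rowOff = x@rowOff[i], colOff = x@colOff[i])
})

#' @rdname ChipGrid-class
#' @export
setMethod("as.data.frame", "ChipGrid", function(x) {
    data.frame(chip_id = chipIds(x), image_id = x@imageId,
               row_index = x@rowIndex, col_index = x@colIndex,
               row_off = x@rowOff, col_off = x@colOff,
               chip_size = x@chipSize, stringsAsFactors = FALSE)
})

setMethod("show", "ChipGrid", function(object) {
    cat(sprintf("ChipGrid '%s': %d windows of %d px over a %d x %d image\n",
                object@imageId, length(object), object@chipSize,
                object@imageDim[1], object@imageDim[2]))
})

# ---------------------------------------------------------------------------
# Chip
# ---------------------------------------------------------------------------

#' A normalized three-band image chip
#'
#' Fixed-size pixel window cut from a raster, with its own affine
#' georeferencing and pixel values normalized to [0, 1].
#'
#' @slot chipId identifier (image id + grid coordinates).
#' @slot pixels chipSize x chipSize x 3 numeric array in [0, 1].
#' @slot transform numeric(6) chip affine.
#' @slot crs coordinate-system tag.
#' @export
setClass("Chip", representation(
    chipId = "character", pixels = "array", transform = "numeric",
    crs = "character"))

setValidity("Chip", function(object) {
    d <- dim(object@pixels)
    msg <- character()
    if (length(d) != 3 || d[3] != 3)
        msg <- c(msg, "chips must have exactly 3 bands")
    rng <- range(object@pixels)
    if (rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "chip values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "Chip", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("Chip '%s': %d x %d x %d, values [%.3f, %.3f]\n",
                object@chipId, d[1], d[2], d[3], min(object@pixels),
                max(object@pixels)))
})
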