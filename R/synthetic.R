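# Synthetic study regions: Voronoi tract mosaics, smooth latent fields,
# rendered three-band rasters and a linear tract-outcome model with known
# explainable variance. Everything is a pure function of the SyntheticConfig.

#' Generate a synthetic study region
#'
#' Tessellates the configured extent into \code{nTracts} Voronoi cells of
#' seeded uniform random sites, clipped to the extent rectangle, so the tract
#' polygons form an exact partition of the region boundary. Each tract
#' receives a "XXXX.YY" style name (unsubdivided, \code{.00}), an 11-digit
#' GEOID-style identifier ending in "00" and a population drawn uniformly from
#' the configured range.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with elements \code{boundary} (the extent rectangle as a
#'   geometry) and \code{tracts} (a [TractSet-class] without outcome rates).
#' @examples
#' reg <- generateRegion(syntheticConfig(seed = 1, nTracts = 4,
#'                                       extent = c(0, 0, 2240, 2240)))
#' length(reg$tracts)
#' @export
generateRegion <- function(config) {
    validObject(config)
    gd <- configGridDim(config)
    if (config@nTracts > gd["nrow"] * gd["ncol"])
        stop("extent can host at most ", gd["nrow"] * gd["ncol"],
             " tracts at >= 1 pixel per tract; got ", config@nTracts)
    ext <- config@extent
    n <- config@nTracts
    dat <- withSeed(config@seed, {
        sites <- cbind(stats::runif(n, ext[1], ext[3]),
                       stats::runif(n, ext[2], ext[4]))
        pop <- round(stats::runif(n, config@populationRange[1],
                                  config@populationRange[2]))
        list(sites = sites, pop = pop)
    })
    cells <- lapply(seq_len(n), function(i)
        ringGeometry(voronoiCell(i, dat$sites, ext)))
    nm <- sprintf("%04d.00", seq_len(n))
    gid <- sprintf("29001%04d00", seq_len(n))
    boundary <- ringGeometry(rectRing(ext[1], ext[2], ext[3], ext[4]))
    tracts <- TractSet(tractId = gid, geometry = cells,
                       population = dat$pop, tractName = nm)
    list(boundary = boundary, tracts = tracts)
}

#' Generate smooth latent scalar fields over the extent
#'
#' Each field is seeded white noise blurred with a Gaussian kernel of sigma
#' \code{fieldLengthScale / pixelSize} pixels (circular boundary), then
#' standardized to mean 0 and variance 1 over the extent. These fields stand
#' in for the spatially structured visual information that links imagery to
#' the outcome.
#'
#' @param config a [SyntheticConfig-class].
#' @param standardize standardize each field to mean 0, variance 1 (default
#'   TRUE; FALSE exposes the raw blurred noise, whose variance shrinks as the
#'   blur grows).
#' @return A \code{nrow x ncol x nLatent} numeric array.
#' @export
generateLatentFields <- function(config, standardize = TRUE) {
    validObject(config)
    span <- c(config@extent[3] - config@extent[1],
              config@extent[4] - config@extent[2])
    if (min(span) < config@fieldLengthScale)
        stop("extent (", min(span), " m) is smaller than one blur radius (",
             config@fieldLengthScale, " m)")
    gd <- configGridDim(config)
    sigma <- config@fieldLengthScale / config@pixelSize
    size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
    maxodd <- min(gd) - (1L - min(gd) %% 2L)
    size <- min(size, maxodd)
    kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
    fields <- array(0, c(gd[["nrow"]], gd[["ncol"]], config@nLatent))
    noise <- withSeed(config@seed + 1L,
        array(stats::rnorm(prod(gd) * config@nLatent),
              c(gd[["nrow"]], gd[["ncol"]], config@nLatent)))
    for (k in seq_len(config@nLatent)) {
        f <- EBImage::filter2(noise[, , k], kern, boundary = "circular")
        if (standardize) f <- (f - mean(f)) / stats::sd(f)
        fields[, , k] <- f
    }
    fields
}

## deterministic band-mixing matrix: band 1 carries the outcome-relevant
## combination (beta direction) so the latent signal lies in the imagery's
## band span; bands 2-3 are seeded distractor mixtures.
defaultMixing <- function(config) {
    K <- config@nLatent
    M <- matrix(0, 3, K)
    b <- config@beta
    M[1, ] <- if (any(b != 0)) b / sqrt(sum(b^2)) else c(1, rep(0, K - 1))
    rnd <- withSeed(config@seed + 4L, matrix(stats::rnorm(2 * K), 2, K))
    for (r in 1:2) {
        v <- rnd[r, ]
        v <- v - sum(v * M[1, ]) * M[1, ] / sum(M[1, ]^2)
        if (sqrt(sum(v^2)) < 1e-8) v <- rnd[r, ]
        M[r + 1, ] <- v / sqrt(sum(v^2))
    }
    M
}

#' Render latent fields into a three-band raster
#'
#' Each band is a fixed affine mixture of the K latent fields plus seeded
#' per-pixel noise, linearly rescaled into the raw integer range
#' \code{[0, rawMax]} that the downstream normalizer divides away. By default
#' the first band's mixing weights are proportional to \code{beta}, so the
#' outcome-relevant latent combination is visible to any imagery-based
#' regressor; the remaining bands carry seeded distractor mixtures.
#'
#' @param fields array from [generateLatentFields()].
#' @param config the same [SyntheticConfig-class].
#' @param mixing optional 3 x K mixing matrix overriding the default.
#' @return A list of one [GeoRaster-class] covering the extent (raw integer
#'   counts).
#' @export
renderRasters <- function(fields, config, mixing = NULL) {
    validObject(config)
    d <- dim(fields)
    stopifnot(d[3] == config@nLatent)
    if (is.null(mixing)) mixing <- defaultMixing(config)
    stopifnot(nrow(mixing) == 3, ncol(mixing) == config@nLatent)
    flat <- matrix(fields, ncol = d[3])
    mixed <- flat %*% t(mixing)                       # pixels x 3
    if (config@pixelNoiseSd > 0)
        mixed <- mixed + withSeed(config@seed + 3L,
            matrix(stats::rnorm(length(mixed), sd = config@pixelNoiseSd),
                   nrow(mixed), 3))
    raw <- array(0, c(d[1], d[2], 3))
    for (b in 1:3) {
        v <- mixed[, b]
        lo <- min(v); hi <- max(v)
        raw[, , b] <- round(config@rawMax * (v - lo) / (hi - lo))
    }
    tr <- northUpTransform(config@extent[1], config@extent[4],
                           config@pixelSize)
    list(GeoRaster(raw, tr, crs = "synthetic:planar",
                   imageId = sprintf("synth%03d", config@seed)))
}

#' Tract means of the latent fields
#'
#' Averages each latent field over the pixels whose centres fall in each
#' tract (same pixel-membership rule as [pixelWeights()]).
#'
#' @param tracts a [TractSet-class] partitioning the extent.
#' @param fields latent field array.
#' @param config the [SyntheticConfig-class].
#' @return n x K matrix of tract means, rows in \code{tractIds(tracts)} order.
#' @export
latentTractMeans <- function(tracts, fields, config) {
    gd <- configGridDim(config)
    tr <- northUpTransform(config@extent[1], config@extent[4],
                           config@pixelSize)
    li <- labelPixels(gd["nrow"], gd["ncol"], tr, tracts)
    lab <- as.vector(li$label)
    if (any(tabulate(lab, nbins = length(li$ids)) == 0))
        stop("some tracts contain no pixel centre; extent too small for nTracts")
    K <- dim(fields)[3]
    Z <- matrix(0, length(li$ids), K,
                dimnames = list(li$ids, paste0("latent", seq_len(K))))
    keep <- lab > 0
    for (k in seq_len(K)) {
        v <- as.vector(fields[, , k])
        Z[, k] <- as.vector(tapply(v[keep], lab[keep], mean))
    }
    Z[tractIds(tracts), , drop = FALSE]
}

#' Draw tract outcome rates over the latent fields
#'
#' \code{outcome_t = outcomeBase + sum_k beta_k z_tk + eps_t} with
#' \code{z_tk} the mean of field k over tract t and seeded
#' \code{eps_t ~ N(0, noiseSd^2)}; rates are clipped to [0, 100]. The
#' returned [SyntheticTruth-class] records the realised across-tract signal
#' and noise variances and \code{trueR2 = signal / (signal + noise)}.
#'
#' @param tracts a [TractSet-class] partitioning the extent.
#' @param fields latent field array from [generateLatentFields()].
#' @param config the [SyntheticConfig-class].
#' @return A list: \code{tracts} (with outcome rates filled in) and
#'   \code{truth}.
#' @export
generateOutcomes <- function(tracts, fields, config) {
    validObject(config)
    Z <- latentTractMeans(tracts, fields, config)
    signal <- drop(Z %*% config@beta)
    eps <- withSeed(config@seed + 2L,
                    stats::rnorm(length(tracts), sd = config@noiseSd))
    rate <- pmin(100, pmax(0, config@outcomeBase + signal + eps))
    outcomeRates(tracts) <- rate
    sv <- stats::var(signal)
    nv <- if (config@noiseSd == 0) 0 else stats::var(eps)
    truth <- new("SyntheticTruth", latentMeans = Z, signalVariance = sv,
                 noiseVariance = nv,
                 trueR2 = if (sv + nv == 0) 0 else sv / (sv + nv))
    list(tracts = tracts, truth = truth)
}

#' Calibrate the outcome noise to a target explainable variance
#'
#' Generates the region and latent fields for the given configuration,
#' measures the realised across-tract signal variance \eqn{s^2} of
#' \code{beta' z}, and returns the configuration with \code{noiseSd} set to
#' \eqn{\sqrt{s^2 (1-\rho)/\rho}} so that the explainable variance fraction
#' equals the target \eqn{\rho}.
#'
#' @param config a [SyntheticConfig-class].
#' @param targetR2 desired \code{trueR2} in (0, 1].
#' @return The configuration with \code{noiseSd} replaced (\code{targetR2 = 1}
#'   sets it to 0).
#' @export
calibrateNoiseSd <- function(config, targetR2) {
    stopifnot(targetR2 > 0, targetR2 <= 1)
    reg <- generateRegion(config)
    fields <- generateLatentFields(config)
    Z <- latentTractMeans(reg$tracts, fields, config)
    s2 <- stats::var(drop(Z %*% config@beta))
    config@noiseSd <- if (targetR2 == 1) 0 else sqrt(s2 * (1 - targetR2) / targetR2)
    validObject(config)
    config
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: region, latent fields, rendered raster and outcomes
#' for one configuration.
#'
#' @param config a [SyntheticConfig-class].
#' @param targetR2 optional explainable-variance target passed to
#'   [calibrateNoiseSd()] before drawing outcomes.
#' @return A list: \code{config} (post-calibration), \code{boundary},
#'   \code{tracts} (with outcomes), \code{fields}, \code{rasters},
#'   \code{truth}.
#' @export
simulateDataset <- function(config, targetR2 = NULL) {
    if (!is.null(targetR2)) config <- calibrateNoiseSd(config, targetR2)
    reg <- generateRegion(config)
    fields <- generateLatentFields(config)
    rasters <- renderRasters(fields, config)
    out <- generateOutcomes(reg$tracts, fields, config)
    list(config = config, boundary = reg$boundary, tracts = out$tracts,
         fields = fields, rasters = rasters, truth = out$truth)
}
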