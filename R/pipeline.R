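# End-to-end convenience: synthetic dataset -> chips -> features -> weights
# -> design matrix -> cross-validated regression.

#' Run the full imagery-to-outcome pipeline on a synthetic region
#'
#' Generates (or accepts) a synthetic dataset, tiles its raster into chips,
#' keeps the usable subset (inside the boundary, intersecting at least one
#' tract), extracts surrogate features, aggregates them to tracts with
#' pixel-count weights, assembles the design matrix and evaluates a k-fold
#' cross-validated regression of outcome on features.
#'
#' @param config a [SyntheticConfig-class].
#' @param targetR2 optional explainable-variance target (see
#'   [calibrateNoiseSd()]).
#' @param spec an \code{ExtractorSpec}; the default uses the surrogate
#'   extractor at D = 256.
#' @param modelKind "forest" (default) or "linear".
#' @param k CV folds.
#' @param chipSize chip edge in pixels.
#' @param nTrees,mtry,ridge model parameters.
#' @param sim optional pre-generated [simulateDataset()] result (overrides
#'   \code{config}/\code{targetR2}).
#' @return A list: \code{sim}, \code{grid} (usable windows), \code{weights},
#'   \code{design} (SummarizedExperiment), \code{cv} (a \code{tsCVSummary}),
#'   \code{inputs} (X, y, ids).
#' @examples
#' \donttest{
#' cfg <- syntheticConfig(seed = 7, nTracts = 40,
#'                        extent = c(0, 0, 4480, 4480), nLatent = 2,
#'                        beta = c(3, 2))
#' res <- runPipeline(cfg, targetR2 = 0.6, k = 5, nTrees = 100)
#' res$cv$means
#' }
#' @export
runPipeline <- function(config, targetR2 = NULL,
                        spec = extractorSpec(kind = "surrogate", D = 256L),
                        modelKind = c("forest", "linear"), k = 10L,
                        chipSize = 224L, nTrees = 300L, mtry = NULL,
                        ridge = 0, sim = NULL) {
    modelKind <- match.arg(modelKind)
    if (is.null(sim)) sim <- simulateDataset(config, targetR2)
    config <- sim$config
    raster <- sim$rasters[[1]]
    d <- dim(raster)
    grid <- planChipGrid(d[2], d[1], chipSize, imageId = raster@imageId,
                         transform = raster@transform, crs = raster@crs)
    weights <- pixelWeights(grid, sim$tracts)
    usable <- filterUsableChips(grid, sim$boundary, weights)
    weights <- weights[weights$chip_id %in% chipIds(usable), , drop = FALSE]
    chips <- cutChips(raster, usable, divisor = config@rawMax)
    features <- chipFeatureMatrix(chips, spec)
    tf <- tractFeatureMatrix(features, weights)
    design <- buildDesignMatrix(tf, sim$tracts)
    inputs <- designInputs(design)
    cv <- kfoldCV(inputs$X, inputs$y, k = k, modelKind = modelKind,
                  seed = config@seed, ridge = ridge, nTrees = nTrees,
                  mtry = mtry)
    list(sim = sim, grid = usable, weights = weights, design = design,
         cv = cv, inputs = inputs)
}
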