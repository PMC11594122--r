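Package: tractscape
Title: Satellite-Imagery Visual Features for Census-Tract Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for modelling area-level health outcomes (such
    as crude obesity prevalence) from medium-resolution satellite imagery.
    Reconciles census-tract identifiers across geography and outcome layers
    with population-weighted rate merging, tiles georeferenced rasters into
    fixed-size image chips, extracts per-chip visual feature vectors through a
    pluggable extractor, aggregates chips and tracts across their pixel-count
    intersection weights, and evaluates cross-validated linear and random
    forest regressions of tract outcome rates on tract-level feature vectors.
    Includes a seeded synthetic-data generator (Voronoi tract mosaics, smooth
    latent fields rendered into three-band rasters, linear outcome model with
    known explainable variance) so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    e1071,
    ranger,
    EBImage,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'aggregate.R'
    'chipper.R'
    'features.R'
    'geometry.R'
    'io.R'
    'pipeline.R'
    'reconcile.R'
    'regression.R'
    'synthetic.R'
    'utils.R'
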