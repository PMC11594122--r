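# On-disk interchange: tract layers as GeoJSON, rasters as TIFF with ESRI
# world-file (+ .crs) sidecars, attribute/weight tables as CSV and a YAML
# manifest tying a synthetic dataset together.

## close a ring for GeoJSON (first vertex repeated last)
closeRing <- function(ring) {
    unname(lapply(seq_len(nrow(ring) + 1L), function(i) {
        j <- if (i > nrow(ring)) 1L else i
        c(ring[j, 1], ring[j, 2])
    }))
}

geomToGeoJSON <- function(geom) {
    list(type = "MultiPolygon",
         coordinates = lapply(geom, function(part) lapply(part, closeRing)))
}

geomFromGeoJSON <- function(g) {
    coords <- g$coordinates
    if (identical(g$type, "Polygon")) coords <- list(coords)
    lapply(coords, function(part) lapply(part, function(ring) {
        m <- do.call(rbind, lapply(ring, function(p)
            c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
        if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
            m <- m[-nrow(m), , drop = FALSE]
        colnames(m) <- c("x", "y")
        m
    }))
}

#' Write a tract layer as GeoJSON
#'
#' Geometries are written as MultiPolygon features with \code{tract_id},
#' \code{tract_name}, \code{population}, \code{outcome_rate} and
#' \code{n_members} properties. Synthetic planar coordinates are written
#' as-is; the CRS tag is recorded in a top-level \code{crs_tag} member.
#'
#' @param tracts a [TractSet-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTractsGeoJSON <- function(tracts, path) {
    feats <- lapply(seq_len(length(tracts)), function(i) {
        list(type = "Feature",
             properties = list(
                 tract_id = tractIds(tracts)[i],
                 tract_name = tractNames(tracts)[i],
                 population = populations(tracts)[i],
                 outcome_rate = outcomeRates(tracts)[i],
                 n_members = nMembers(tracts)[i]),
             geometry = geomToGeoJSON(tractGeometry(tracts)[[i]]))
    })
    fc <- list(type = "FeatureCollection", crs_tag = tracts@crs,
               features = feats)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    invisible(path)
}

#' Read a tract layer from GeoJSON
#'
#' Accepts Polygon or MultiPolygon features; attributes are read from the
#' properties written by [writeTractsGeoJSON()] (absent attributes become
#' NA / defaults).
#'
#' @param path GeoJSON file path.
#' @return A [TractSet-class].
#' @export
readTractsGeoJSON <- function(path) {
    fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    stopifnot(identical(fc$type, "FeatureCollection"))
    n <- length(fc$features)
    prop <- function(f, name, default) {
        v <- f$properties[[name]]
        if (is.null(v)) default else v
    }
    TractSet(
        tractId = vapply(fc$features, prop, character(1), name = "tract_id",
                         default = NA_character_),
        geometry = lapply(fc$features, function(f) geomFromGeoJSON(f$geometry)),
        population = vapply(fc$features, function(f)
            as.numeric(prop(f, "population", 0)), numeric(1)),
        outcomeRate = vapply(fc$features, function(f)
            as.numeric(prop(f, "outcome_rate", NA_real_)), numeric(1)),
        tractName = vapply(fc$features, function(f)
            as.character(prop(f, "tract_name", NA_character_)), character(1)),
        nMembers = vapply(fc$features, function(f)
            as.integer(prop(f, "n_members", 1L)), integer(1)),
        crs = if (is.null(fc$crs_tag)) "unspecified" else fc$crs_tag)
}

#' Write a raster as TIFF with world-file georeferencing
#'
#' Pixel values (raw non-negative integers up to 65535) are stored in a
#' 16-bit TIFF; the affine transform goes into an ESRI world file
#' (\code{.tfw}: pixel sizes, rotation terms and the map coordinates of the
#' top-left pixel centre) and the CRS tag into a \code{.crs} sidecar.
#'
#' @param raster a [GeoRaster-class].
#' @param path output \code{.tif} path.
#' @return \code{path}, invisibly.
#' @export
writeRasterTiff <- function(raster, path) {
    v <- raster@values
    if (min(v) < 0 || max(v) > 65535)
        stop("raster values must be raw integers in [0, 65535]")
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    t <- raster@transform
    cx <- t[3] + t[1] * 0.5 + t[2] * 0.5
    cy <- t[6] + t[4] * 0.5 + t[5] * 0.5
    writeLines(format(c(t[1], t[4], t[2], t[5], cx, cy), digits = 17),
               sub("\\.tif{1,2}$", ".tfw", path))
    writeLines(raster@crs, sub("\\.tif{1,2}$", ".crs", path))
    invisible(path)
}

#' Read a raster written by [writeRasterTiff()]
#'
#' @param path \code{.tif} path (expects the \code{.tfw} and \code{.crs}
#'   sidecars alongside).
#' @param imageId identifier for the returned raster.
#' @return A [GeoRaster-class] with the original integer values.
#' @export
readRasterTiff <- function(path, imageId = sub("\\.tif{1,2}$", "",
                                               basename(path))) {
    v <- round(tiff::readTIFF(path) * 65535)
    if (length(dim(v)) == 2) dim(v) <- c(dim(v), 1L)
    tfw <- as.numeric(readLines(sub("\\.tif{1,2}$", ".tfw", path)))
    a <- tfw[1]; d <- tfw[2]; b <- tfw[3]; e <- tfw[4]
    tr <- c(a, b, tfw[5] - a * 0.5 - b * 0.5,
            d, e, tfw[6] - d * 0.5 - e * 0.5)
    crsPath <- sub("\\.tif{1,2}$", ".crs", path)
    crs <- if (file.exists(crsPath)) readLines(crsPath)[1] else "unspecified"
    GeoRaster(v * 1.0, tr, crs = crs, imageId = imageId)
}

#' Read a product-metadata table
#'
#' @param path CSV with columns \code{product_id}, \code{footprint_wkt},
#'   \code{cloud_pct} and optionally \code{area}, \code{date}.
#' @return data.frame suitable for [selectProducts()].
#' @export
readProductMeta <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("product_id", "footprint_wkt", "cloud_pct")
    if (!all(need %in% names(df)))
        stop("product metadata must have columns ",
             paste(need, collapse = ", "))
    df
}

#' Write a synthetic dataset to a directory
#'
#' Writes the tract layer and region boundary as GeoJSON, the rendered
#' raster(s) as 16-bit TIFF + world file, the outcomes and ground truth as
#' CSV, and a YAML manifest recording the full configuration.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeTractsGeoJSON(sim$tracts, file.path(dir, "tracts.geojson"))
    boundarySet <- TractSet("boundary", list(sim$boundary), population = 0)
    writeTractsGeoJSON(boundarySet, file.path(dir, "boundary.geojson"))
    rasterFiles <- character()
    for (r in sim$rasters) {
        f <- file.path(dir, paste0(r@imageId, ".tif"))
        writeRasterTiff(r, f)
        rasterFiles <- c(rasterFiles, basename(f))
    }
    utils::write.csv(
        data.frame(tract_id = tractIds(sim$tracts),
                   population = populations(sim$tracts),
                   outcome_rate = outcomeRates(sim$tracts)),
        file.path(dir, "outcomes.csv"), row.names = FALSE)
    utils::write.csv(
        data.frame(tract_id = rownames(sim$truth@latentMeans),
                   sim$truth@latentMeans),
        file.path(dir, "latent_means.csv"), row.names = FALSE)
    cfg <- sim$config
    manifest <- list(
        config = list(seed = cfg@seed, n_tracts = cfg@nTracts,
                      extent = cfg@extent, pixel_size = cfg@pixelSize,
                      n_latent = cfg@nLatent,
                      field_length_scale = cfg@fieldLengthScale,
                      beta = cfg@beta, noise_sd = cfg@noiseSd,
                      outcome_base = cfg@outcomeBase,
                      population_range = cfg@populationRange,
                      pixel_noise_sd = cfg@pixelNoiseSd,
                      raw_max = cfg@rawMax),
        truth = list(signal_variance = sim$truth@signalVariance,
                     noise_variance = sim$truth@noiseVariance,
                     true_r2 = sim$truth@trueR2),
        files = list(tracts = "tracts.geojson",
                     boundary = "boundary.geojson",
                     rasters = rasterFiles, outcomes = "outcomes.csv",
                     latent_means = "latent_means.csv"))
    mf <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(manifest, mf)
    invisible(mf)
}

#' Join outcome/population attributes from a CSV onto a tract layer
#'
#' @param tracts a [TractSet-class].
#' @param attrs data.frame (or CSV path) keyed by tract id.
#' @param idCol,rateCol,popCol column names in \code{attrs}.
#' @return The tract set with outcome rates (and populations, when present)
#'   filled in; unmatched tracts keep NA rates.
#' @export
joinAttributes <- function(tracts, attrs, idCol = "tract_id",
                           rateCol = "outcome_rate", popCol = "population") {
    if (is.character(attrs)) attrs <- utils::read.csv(attrs,
                                                      stringsAsFactors = FALSE,
                                                      colClasses = "character")
    m <- match(tractIds(tracts), as.character(attrs[[idCol]]))
    if (rateCol %in% names(attrs))
        tracts@outcomeRate <- as.numeric(attrs[[rateCol]])[m]
    if (popCol %in% names(attrs)) {
        p <- as.numeric(attrs[[popCol]])[m]
        tracts@population <- ifelse(is.na(p), tracts@population, p)
    }
    validObject(tracts)
    tracts
}
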