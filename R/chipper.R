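# Raster product selection, [0,1] normalization and tiling into fixed-size
# georeferenced chips.

#' Select non-redundant raster products
#'
#' Among products sharing an identical footprint (the same acquisition tile),
#' keeps the one with the largest area and, at equal area, the lowest cloud
#' percentage; then drops any product on the explicit exclusion list (the
#' auditable stand-in for manual removal of partially overlapping products).
#'
#' @param products data.frame with columns \code{product_id},
#'   \code{footprint_wkt}, \code{cloud_pct}, optionally \code{area} and
#'   \code{date}. Missing \code{area} is filled with 0 (footprint parsing is
#'   not attempted).
#' @param exclusions character vector of product ids to drop after filtering.
#' @return The filtered data.frame, original row order preserved.
#' @export
selectProducts <- function(products, exclusions = character()) {
    stopifnot(is.data.frame(products),
              all(c("product_id", "footprint_wkt", "cloud_pct") %in%
                  names(products)))
    if (anyDuplicated(products$product_id))
        stop("duplicate product_id(s): ",
             paste(unique(products$product_id[duplicated(products$product_id)]),
                   collapse = ", "))
    if (any(products$cloud_pct < 0 | products$cloud_pct > 100))
        stop("cloud_pct must lie in [0, 100]")
    area <- if ("area" %in% names(products)) products$area else
        rep(0, nrow(products))
    keep <- unlist(lapply(split(seq_len(nrow(products)),
                                products$footprint_wkt), function(idx) {
        a <- area[idx]
        best <- idx[a == max(a)]
        best[which.min(products$cloud_pct[best])]
    }))
    keep <- sort(keep)
    out <- products[keep, , drop = FALSE]
    out <- out[!(out$product_id %in% exclusions), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Normalize raw integer pixel values to [0, 1]
#'
#' Divides by a fixed divisor (default 10000, the usual surface-reflectance
#' integer convention) and optionally clips to [0, 1]. Monotone and
#' order-preserving below the clip point; the identity on already-normalized
#' data with divisor 1.
#'
#' @param raw numeric array/matrix of non-negative raw values.
#' @param divisor positive normalization divisor.
#' @param clip clip to [0, 1] (default TRUE).
#' @return Array of the same shape with values in [0, 1] when clipping.
#' @export
normalizeImage <- function(raw, divisor = 10000, clip = TRUE) {
    stopifnot(divisor > 0)
    if (any(raw < 0)) stop("negative raw pixel values")
    v <- raw / divisor
    if (clip) v <- pmin(v, 1)
    v
}

#' Plan the chip-window grid over an image
#'
#' Lays out \code{ceiling(width/chipSize) x ceiling(height/chipSize)} windows
#' of exactly \code{chipSize} pixels. Interior windows abut without overlap;
#' a ragged final row/column is clamped inward so its window ends exactly at
#' the image edge, keeping every window full-size and inside bounds (no
#' zero-padding).
#'
#' @param width,height image dimensions in pixels.
#' @param chipSize window edge in pixels (default 224).
#' @param imageId identifier recorded in the grid.
#' @param transform image affine (6 coefficients).
#' @param crs coordinate-system tag.
#' @return A [ChipGrid-class] in row-major window order.
#' @examples
#' length(planChipGrid(10980, 10980))  # 2500
#' @export
planChipGrid <- function(width, height, chipSize = 224L, imageId = "image",
                         transform = c(1, 0, 0, 0, -1, 0),
                         crs = "synthetic:planar") {
    chipSize <- as.integer(chipSize)
    if (width < chipSize || height < chipSize)
        stop("image (", width, " x ", height,
             ") is smaller than the chip size ", chipSize)
    ncolw <- as.integer(ceiling(width / chipSize))
    nroww <- as.integer(ceiling(height / chipSize))
    ri <- rep(seq_len(nroww) - 1L, each = ncolw)
    ci <- rep(seq_len(ncolw) - 1L, times = nroww)
    roff <- pmin(ri * chipSize, as.integer(height) - chipSize)
    coff <- pmin(ci * chipSize, as.integer(width) - chipSize)
    new("ChipGrid", imageId = imageId, rowIndex = ri, colIndex = ci,
        rowOff = roff, colOff = coff, chipSize = chipSize,
        imageDim = as.integer(c(height, width)),
        transform = as.numeric(transform), crs = crs)
}

#' Affine transform of a chip window
#'
#' Translates the parent image affine by the window's pixel offsets, so that
#' chip pixel (0, 0) maps to the same map coordinate as image pixel
#' (colOff, rowOff).
#'
#' @param grid a [ChipGrid-class].
#' @param i window index (or chip id).
#' @param imageTransform optional override of the parent affine.
#' @return Numeric(6) affine of the chip.
#' @export
chipTransform <- function(grid, i, imageTransform = grid@transform) {
    if (is.character(i)) i <- match(i, chipIds(grid))
    stopifnot(length(i) == 1, !is.na(i))
    t <- imageTransform
    co <- grid@colOff[i]; ro <- grid@rowOff[i]
    c(t[1], t[2], t[3] + t[1] * co + t[2] * ro,
      t[4], t[5], t[6] + t[4] * co + t[5] * ro)
}

#' Cut (and normalize) one chip from a raster
#'
#' @param raster a [GeoRaster-class] of raw integer values.
#' @param grid the [ChipGrid-class] planned on this raster.
#' @param i window index or chip id.
#' @param divisor,clip passed to [normalizeImage()].
#' @return A [Chip-class] with values in [0, 1].
#' @export
cutChip <- function(raster, grid, i, divisor = 10000, clip = TRUE) {
    if (is.character(i)) i <- match(i, chipIds(grid))
    d <- dim(raster@values)
    cs <- grid@chipSize
    ro <- grid@rowOff[i]; co <- grid@colOff[i]
    if (ro < 0 || co < 0 || ro + cs > d[1] || co + cs > d[2])
        stop("window ", i, " lies outside the raster bounds")
    px <- normalizeImage(raster@values[(ro + 1):(ro + cs),
                                       (co + 1):(co + cs), , drop = FALSE],
                         divisor = divisor, clip = clip)
    new("Chip", chipId = chipIds(grid)[i], pixels = px,
        transform = chipTransform(grid, i, raster@transform),
        crs = raster@crs)
}

#' Stream chips through a function
#'
#' Applies \code{FUN} to each chip in row-major window order, holding only
#' one chip in memory at a time (the streaming contract for full-size
#' imagery).
#'
#' @param raster a [GeoRaster-class].
#' @param grid the [ChipGrid-class] planned on this raster.
#' @param FUN function of a [Chip-class].
#' @param divisor,clip passed to [normalizeImage()].
#' @return List of \code{FUN} results, one per window, named by chip id.
#' @export
chipApply <- function(raster, grid, FUN, divisor = 10000, clip = TRUE) {
    out <- vector("list", length(grid))
    for (i in seq_len(length(grid)))
        out[[i]] <- FUN(cutChip(raster, grid, i, divisor, clip))
    names(out) <- chipIds(grid)
    out
}

#' Cut all chips of a raster
#'
#' Materializes every window as a [Chip-class]; convenient for desk-scale
#' rasters (use [chipApply()] to stream full-size imagery).
#'
#' @inheritParams chipApply
#' @return Named list of [Chip-class] objects.
#' @export
cutChips <- function(raster, grid, divisor = 10000, clip = TRUE) {
    chipApply(raster, grid, identity, divisor = divisor, clip = clip)
}
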