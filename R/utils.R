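# Shared internal helpers.

## Evaluate expr with a locally fixed RNG state, restoring the caller's
## .Random.seed afterwards, so seeded generator internals never disturb the
## global random stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## north-up affine from extent + pixel size: pixel (0,0) corner at
## (xmin, ymax), rows growing southwards
northUpTransform <- function(xmin, ymax, pixelSize) {
    c(pixelSize, 0, xmin, 0, -pixelSize, ymax)
}

## map coordinates of pixel centres for 0-based col/row vectors
pixelCenters <- function(transform, col, row) {
    list(x = transform[3] + transform[1] * (col + 0.5) + transform[2] * (row + 0.5),
         y = transform[6] + transform[4] * (col + 0.5) + transform[5] * (row + 0.5))
}

## label a nrow x ncol pixel grid by tract (1-based index into `order`-sorted
## geometries; 0 = unassigned). Ties on shared boundaries resolve to the
## lexicographically smallest tract id because geometries are scanned in
## sorted-id order with a boundary-inclusive test.
labelPixels <- function(nrow, ncol, transform, tracts) {
    ord <- order(tractIds(tracts), method = "radix")
    geoms <- tractGeometry(tracts)[ord]
    bb <- do.call(rbind, lapply(geoms, geometryBBox))
    lab <- label_pixels_cpp(as.integer(nrow), as.integer(ncol),
                            as.numeric(transform), geoms, bb)
    list(label = lab, ids = tractIds(tracts)[ord])
}

## raster grid dimensions implied by a config extent
configGridDim <- function(config) {
    nx <- round((config@extent[3] - config@extent[1]) / config@pixelSize)
    ny <- round((config@extent[4] - config@extent[2]) / config@pixelSize)
    c(nrow = ny, ncol = nx)
}
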