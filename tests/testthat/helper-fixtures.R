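# Shared fixture builders and independent oracles.

## a unit-square tract geometry at (x0, y0) with side s
squareGeom <- function(x0, y0, s = 1) {
    ringGeometry(rectRing(x0, y0, x0 + s, y0 + s))
}

## tract layer with the printed composition of a subdivided tract-name
## inventory: nPlain unsubdivided names plus nSub subdivided names spread
## over nBases base names (every base present at least twice).
nameFixture <- function(nPlain, nSub, nBases) {
    stopifnot(nSub >= 2 * nBases)
    plain <- sprintf("%04d.00", seq_len(nPlain))
    reps <- rep(2L, nBases)
    extra <- nSub - 2L * nBases
    if (extra > 0) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
    subBase <- 5000L + seq_len(nBases)
    sub <- unlist(lapply(seq_len(nBases), function(i)
        sprintf("%04d.%02d", subBase[i], seq_len(reps[i]))))
    nm <- c(plain, sub)
    n <- length(nm)
    TractSet(tractId = sprintf("29%09d", seq_len(n)),
             geometry = lapply(seq_len(n), function(i)
                 squareGeom((i - 1) %% 60, (i - 1) %/% 60)),
             population = rep(100, n), outcomeRate = rep(35, n),
             tractName = nm)
}

## outcome layer keyed by all-digit GEOIDs: nPlain ids ending "00" plus nSub
## subdivided ids over nBases bases
geoidFixture <- function(nPlain, nSub, nBases) {
    stopifnot(nSub >= 2 * nBases)
    plain <- sprintf("29001%04d00", seq_len(nPlain))
    reps <- rep(2L, nBases)
    extra <- nSub - 2L * nBases
    if (extra > 0) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
    sub <- unlist(lapply(seq_len(nBases), function(i)
        sprintf("29002%04d%02d", i, seq_len(reps[i]))))
    ids <- c(plain, sub)
    n <- length(ids)
    TractSet(tractId = ids,
             geometry = lapply(seq_len(n), function(i)
                 squareGeom((i - 1) %% 60, (i - 1) %/% 60)),
             population = rep(50, n) + seq_len(n) %% 7 * 10,
             outcomeRate = 25 + (seq_len(n) %% 20))
}

## independent per-pixel oracle for chip-tract pixel counting: loops over
## every pixel centre of window i and assigns it to the first tract (sorted
## by id) containing it, using pracma::inpolygon (single-ring tracts only).
bruteforceWeights <- function(grid, i, tracts) {
    cs <- grid@chipSize
    tr <- chipTransform(grid, i)
    ids <- sort(tractIds(tracts))
    rings <- lapply(ids, function(id)
        tractGeometry(tracts)[[match(id, tractIds(tracts))]][[1]][[1]])
    counts <- stats::setNames(integer(length(ids)), ids)
    for (row in seq_len(cs) - 1L) {
        for (col in seq_len(cs) - 1L) {
            px <- tr[3] + tr[1] * (col + 0.5) + tr[2] * (row + 0.5)
            py <- tr[6] + tr[4] * (col + 0.5) + tr[5] * (row + 0.5)
            for (k in seq_along(ids)) {
                r <- rings[[k]]
                if (pracma::inpolygon(px, py, r[, 1], r[, 2],
                                      boundary = TRUE)) {
                    counts[k] <- counts[k] + 1L
                    break
                }
            }
        }
    }
    data.frame(chip_id = chipIds(grid)[i], tract_id = ids[counts > 0],
               pixel_count = as.integer(counts[counts > 0]),
               stringsAsFactors = FALSE)
}

## small raw-integer raster with a seeded random pattern
toyRaster <- function(nrow, ncol, seed = 1, rawMax = 10000,
                      xmin = 0, ymax = nrow, pixelSize = 1) {
    set.seed(seed)
    vals <- array(sample.int(rawMax + 1, nrow * ncol * 3, replace = TRUE) - 1L,
                  c(nrow, ncol, 3))
    GeoRaster(vals, c(pixelSize, 0, xmin, 0, -pixelSize, ymax),
              imageId = sprintf("toy%02d", seed))
}

## constant-value chip helper
constantChip <- function(value, size = 16, id = "chip") {
    new("Chip", chipId = id, pixels = array(value, c(size, size, 3)),
        transform = c(1, 0, 0, 0, -1, size), crs = "synthetic:planar")
}

## small config used across synthetic tests: 1120 m square, 4 m pixels
smallConfig <- function(seed = 1, nTracts = 12, nLatent = 2,
                        beta = c(3, 2), ...) {
    syntheticConfig(seed = seed, nTracts = nTracts,
                    extent = c(0, 0, 1120, 1120), pixelSize = 4,
                    nLatent = nLatent, fieldLengthScale = 120,
                    beta = beta, ...)
}
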