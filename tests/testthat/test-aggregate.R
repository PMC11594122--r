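test_that("pixel counting handles full, half and disjoint tract covers", {
    tr <- c(10, 0, 0, 0, -10, 2240)      # 224 x 224 px, 10 m pixels
    grid <- planChipGrid(224, 224, 224, transform = tr)
    full <- TractSet("29001000100", list(squareGeom(-10, -10, 2260)),
                     population = 10, outcomeRate = 39.2)
    w <- pixelWeights(grid, full)
    expect_equal(w$pixel_count, 224L * 224L)    # 50176
    # left half split between pixel columns 111/112: boundary at x = 1120
    half <- TractSet("29001000200",
                     list(ringGeometry(rectRing(-10, -10, 1120, 2250))),
                     population = 10, outcomeRate = 30)
    wh <- pixelWeights(grid, half)
    expect_equal(wh$pixel_count, 112L * 224L)   # 25088
    # disjoint polygon yields no weight rows
    far <- TractSet("29001000300", list(squareGeom(9000, 9000, 100)),
                    population = 10, outcomeRate = 30)
    expect_equal(nrow(pixelWeights(grid, far)), 0L)
    # CRS mismatch is refused
    other <- full; other@crs <- "EPSG:32615"
    expect_error(pixelWeights(grid, other), "mismatch")
})

test_that("pixel counting matches the brute-force per-pixel oracle", {
    skip_if_not_installed("pracma")
    set.seed(21)
    for (rep in 1:4) {
        npx <- sample(c(32, 48, 64), 1)
        tr <- c(1, 0, 0, 0, -1, npx)
        grid <- planChipGrid(npx, npx, npx, transform = tr)
        nT <- sample(2:5, 1)
        sites <- cbind(runif(nT, 0, npx), runif(nT, 0, npx))
        geoms <- lapply(seq_len(nT), function(i)
            ringGeometry(voronoiCell(i, sites, c(0, 0, npx, npx))))
        tracts <- TractSet(sprintf("29%09d", sample(1e6, nT)),
                           geometry = geoms,
                           population = rep(10, nT),
                           outcomeRate = runif(nT, 23, 54))
        mine <- pixelWeights(grid, tracts)
        oracle <- bruteforceWeights(grid, 1, tracts)
        mine <- mine[order(mine$tract_id), ]
        expect_equal(mine$tract_id, oracle$tract_id)
        expect_equal(mine$pixel_count, oracle$pixel_count)
        # partition conservation: counts sum to the full chip
        expect_equal(sum(mine$pixel_count), npx * npx)
    }
})

test_that("usable-chip filtering enforces coverage and tract overlap", {
    r <- toyRaster(64, 64, seed = 2, xmin = 0, ymax = 64)
    grid <- planChipGrid(64, 64, 16, transform = r@transform, crs = r@crs)
    # boundary covering only the west half
    boundary <- ringGeometry(rectRing(-1, -1, 33, 65))
    tracts <- TractSet("29001000100", list(squareGeom(0, 32, 32)),
                       population = 5, outcomeRate = 40)
    w <- pixelWeights(grid, tracts)
    usable <- filterUsableChips(grid, boundary, w)
    df <- as.data.frame(usable)
    # west-half chips: col 0..1 of 4; tract covers the NW quadrant
    expect_true(all(df$col_index <= 1))
    expect_true(all(df$row_index <= 1))
    expect_equal(length(usable), 4L)
    # chip straddling the boundary is discarded even with tract overlap
    expect_false(any(df$col_index == 2))
    # inside the boundary but no tract: discarded
    expect_false(any(df$row_index > 1))
})

test_that("weighted aggregations follow the pixel-count weighted mean", {
    feats <- cbind(c1 = c(0, 0), c2 = c(4, 8))
    rownames(feats) <- c("f0", "f1")
    wEq <- data.frame(chip_id = c("c1", "c2"), tract_id = "t",
                      pixel_count = c(10L, 10L))
    expect_equal(tractFeature(feats, wEq)$values, c(f0 = 2, f1 = 4))
    w13 <- data.frame(chip_id = c("c1", "c2"), tract_id = "t",
                      pixel_count = c(1L, 3L))
    tf <- tractFeature(feats, w13)
    expect_equal(tf$values, c(f0 = 3, f1 = 6))
    expect_equal(tf$totalWeight, 4L); expect_equal(tf$nChips, 2L)
    # single chip: identity
    expect_equal(tractFeature(feats, wEq[1, ])$values, c(f0 = 0, f1 = 0))
    expect_error(tractFeature(feats, wEq[0, ]), "zero total")
    expect_error(tractFeature(feats,
        data.frame(chip_id = "cX", tract_id = "t", pixel_count = 5L)),
        "missing chip")

    tracts <- TractSet(c("a", "b"),
                       list(squareGeom(0, 0), squareGeom(1, 0)),
                       population = c(1, 1), outcomeRate = c(23.0, 53.7))
    wc <- data.frame(chip_id = "c", tract_id = c("a", "b"),
                     pixel_count = c(25088L, 25088L))
    expect_equal(chipOutcome(tracts, wc)$rate, 38.35)
    one <- TractSet("a", list(squareGeom(0, 0)), 1, outcomeRate = 39.2)
    expect_equal(chipOutcome(one, wc[1, ])$rate, 39.2)
    eq <- TractSet(c("a", "b"), list(squareGeom(0, 0), squareGeom(1, 0)),
                   c(1, 1), outcomeRate = c(30, 50))
    expect_equal(chipOutcome(eq, wc)$rate, 40)
    expect_error(chipOutcome(tracts, wc[0, ]), "zero pixel weight")
})

test_that("aggregated values match direct summation and stay convex", {
    set.seed(31)
    D <- 6; nChips <- 8; nTracts <- 3
    feats <- matrix(rnorm(D * nChips), D, nChips,
                    dimnames = list(NULL, sprintf("c%02d", 1:nChips)))
    w <- data.frame(chip_id = rep(colnames(feats), each = nTracts),
                    tract_id = rep(sprintf("t%d", 1:nTracts), nChips),
                    pixel_count = sample.int(100, nChips * nTracts,
                                             replace = TRUE))
    tf <- tractFeatureMatrix(feats, w)
    for (t in sprintf("t%d", 1:nTracts)) {
        wt <- w[w$tract_id == t, ]
        direct <- rowSums(sweep(feats[, wt$chip_id], 2, wt$pixel_count,
                                "*")) / sum(wt$pixel_count)
        expect_equal(tf$values[, t], direct, tolerance = 1e-12)
        expect_true(all(tf$values[, t] >=
                        apply(feats[, wt$chip_id], 1, min) - 1e-12))
        expect_true(all(tf$values[, t] <=
                        apply(feats[, wt$chip_id], 1, max) + 1e-12))
    }
    # order invariance
    wShuf <- w[sample.int(nrow(w)), ]
    expect_equal(tractFeatureMatrix(feats, wShuf)$values, tf$values)
})

test_that("the design matrix joins features and outcomes by tract id", {
    feats <- matrix(1:12, 4, 3, dimnames = list(sprintf("f%d", 1:4),
                                                c("a", "b", "c")))
    tfm <- list(values = feats,
                totalWeight = c(a = 10, b = 20, c = 30),
                nChips = c(a = 1L, b = 2L, c = 3L))
    tracts <- TractSet(c("a", "b", "c", "d"),
                       lapply(0:3, function(i) squareGeom(i, 0)),
                       population = rep(10, 4),
                       outcomeRate = c(30, NA, 50, 40))
    expect_message(se <- buildDesignMatrix(tfm, tracts), "excluding 2")
    expect_equal(dim(se), c(4L, 2L))
    expect_identical(colnames(se), c("a", "c"))
    expect_equal(S4Vectors::metadata(se)$excluded, c("b", "d"))
    di <- designInputs(se)
    expect_equal(di$X["a", ], c(f1 = 1, f2 = 2, f3 = 3, f4 = 4))
    expect_equal(di$y, c(30, 50))
    # row for each tract equals its aggregated feature vector exactly
    expect_equal(unname(di$X["c", ]), unname(feats[, "c"]))
    bad <- TractSet("z", list(squareGeom(9, 9)), 1, outcomeRate = 33)
    expect_error(buildDesignMatrix(tfm, bad), "no tract")
})
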