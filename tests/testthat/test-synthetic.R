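test_that("identical configurations give bit-identical regions", {
    cfg <- smallConfig(seed = 9, nTracts = 8)
    a <- generateRegion(cfg)
    b <- generateRegion(cfg)
    expect_identical(a$tracts@geometry, b$tracts@geometry)
    expect_identical(populations(a$tracts), populations(b$tracts))
    expect_identical(tractNames(a$tracts)[1], "0001.00")
    expect_true(all(grepl("^[0-9]{11}$", tractIds(a$tracts))))
    expect_true(all(populations(a$tracts) >= cfg@populationRange[1] &
                    populations(a$tracts) <= cfg@populationRange[2]))
})

test_that("region generation rejects more tracts than pixels", {
    cfg <- syntheticConfig(seed = 1, nTracts = 30, extent = c(0, 0, 50, 50),
                           pixelSize = 10, nLatent = 1, beta = 1,
                           fieldLengthScale = 20)
    expect_error(generateRegion(cfg), "host at most")
})

test_that("latent fields are seeded, standardized and smooth", {
    cfg <- syntheticConfig(seed = 5, nTracts = 4, extent = c(0, 0, 2048, 2048),
                           pixelSize = 4, nLatent = 2, beta = c(1, 1),
                           fieldLengthScale = 160)
    f1 <- generateLatentFields(cfg)
    f2 <- generateLatentFields(cfg)
    expect_identical(f1, f2)
    expect_equal(dim(f1), c(512L, 512L, 2L))
    for (k in 1:2) {
        expect_equal(mean(f1[, , k]), 0, tolerance = 0.02)
        expect_equal(var(as.vector(f1[, , k])), 1, tolerance = 0.05)
    }
    # smoothness: neighbouring pixels are highly correlated
    v <- f1[, , 1]
    expect_gt(cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ])), 0.95)
    # blur larger than the extent is rejected
    cfgBig <- smallConfig(); cfgBig@fieldLengthScale <- 5000
    expect_error(generateLatentFields(cfgBig), "blur radius")
    # raw blurred noise loses variance as the blur grows
    cfgA <- smallConfig(seed = 5, nLatent = 1, beta = 1)
    cfgB <- cfgA; cfgB@fieldLengthScale <- 500
    vA <- var(as.vector(generateLatentFields(cfgA, standardize = FALSE)))
    vB <- var(as.vector(generateLatentFields(cfgB, standardize = FALSE)))
    expect_lt(vB, vA / 5)
})

test_that("rendered bands are monotone in the latent field and round-trip", {
    cfg <- smallConfig(seed = 2, nTracts = 4, nLatent = 1, beta = 2,
                       pixelNoiseSd = 0)
    f <- generateLatentFields(cfg)
    r <- renderRasters(f, cfg, mixing = matrix(c(1, 1, 1), 3, 1))[[1]]
    expect_equal(dim(r@values)[3], 3)
    expect_true(all(r@values >= 0 & r@values <= cfg@rawMax))
    # band 1 is a monotone transform of field 1
    o <- order(as.vector(f[, , 1]))
    b <- as.vector(r@values[, , 1])[o]
    expect_true(all(diff(b) >= 0))
    # disk round trip preserves pixels and georeferencing
    tf <- file.path(tempdir(), "synth.tif")
    writeRasterTiff(r, tf)
    r2 <- readRasterTiff(tf)
    expect_equal(r2@values, r@values)
    expect_equal(r2@transform, r@transform)
    expect_identical(r2@crs, r@crs)
})

test_that("per-chip band means track the latent field at low pixel noise", {
    cfg <- syntheticConfig(seed = 0, nTracts = 4, extent = c(0, 0, 2240, 2240),
                           pixelSize = 10, nLatent = 1, beta = 1,
                           fieldLengthScale = 200, pixelNoiseSd = 0.1)
    f <- generateLatentFields(cfg)
    r <- renderRasters(f, cfg)[[1]]
    grid <- planChipGrid(224, 224, 56, imageId = r@imageId,
                         transform = r@transform, crs = r@crs)
    bandMean <- fieldMean <- numeric(length(grid))
    for (i in seq_len(length(grid))) {
        ro <- grid@rowOff[i]; co <- grid@colOff[i]
        idx <- list(ro + 1:56, co + 1:56)
        bandMean[i] <- mean(r@values[idx[[1]], idx[[2]], 1])
        fieldMean[i] <- mean(f[idx[[1]], idx[[2]], 1])
    }
    expect_gt(cor(bandMean, fieldMean), 0.9)
})

test_that("outcomes follow the linear latent model with seeded noise", {
    cfg <- smallConfig(seed = 7, nTracts = 15, noiseSd = 0)
    reg <- generateRegion(cfg)
    f <- generateLatentFields(cfg)
    out <- generateOutcomes(reg$tracts, f, cfg)
    expect_equal(trueR2(out$truth), 1)
    # noiseless: outcome is exactly base + beta . latent means
    Z <- out$truth@latentMeans
    expect_equal(outcomeRates(out$tracts),
                 unname(cfg@outcomeBase + drop(Z %*% cfg@beta)),
                 tolerance = 1e-12)
    # regression on the latent means recovers everything
    fit <- fitLinear(Z, outcomeRates(out$tracts))
    pred <- predict(fit, Z)
    expect_equal(unname(computeMetrics(outcomeRates(out$tracts), pred, 2)["r2"]),
                 1, tolerance = 1e-9)
    # zero coefficients give zero explainable variance
    cfg0 <- smallConfig(seed = 7, nTracts = 15, beta = c(0, 0))
    out0 <- generateOutcomes(reg$tracts, f, cfg0)
    expect_equal(trueR2(out0$truth), 0)
    # rates stay in [0, 100]
    expect_true(all(outcomeRates(out$tracts) >= 0 &
                    outcomeRates(out$tracts) <= 100))
})

test_that("noise calibration hits the target explainable variance", {
    r2s <- vapply(1:20, function(s) {
        cfg <- calibrateNoiseSd(smallConfig(seed = s, nTracts = 60), 0.6)
        reg <- generateRegion(cfg)
        f <- generateLatentFields(cfg)
        trueR2(generateOutcomes(reg$tracts, f, cfg)$truth)
    }, numeric(1))
    expect_lt(abs(mean(r2s) - 0.6), 0.05)
})
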