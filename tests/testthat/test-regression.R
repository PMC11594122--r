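test_that("linear fitting recovers, interpolates and shrinks as expected", {
    set.seed(1)
    # identifiable case: exact recovery
    X <- matrix(rnorm(200 * 5), 200, 5)
    beta <- c(2, -1, 0.5, 3, 0)
    y <- drop(X %*% beta) + 7
    fit <- fitLinear(X, y)
    expect_equal(fit$coefficients, beta, tolerance = 1e-9)
    expect_equal(fit$intercept, 7, tolerance = 1e-9)
    expect_equal(unname(computeMetrics(y, predict(fit, X), 5)["r2"]), 1)
    # agreement with lm() as an independent check
    lmfit <- lm(y2 ~ ., data = data.frame(y2 = y + rnorm(200), X))
    fit2 <- fitLinear(X, y + resid(lmfit) + fitted(lmfit) - y)
    expect_equal(unname(fit2$coefficients), unname(coef(lmfit)[-1]),
                 tolerance = 1e-8)
    # p > n: minimum-norm solution interpolates the training data
    Xp <- matrix(rnorm(20 * 100), 20, 100)
    yp <- rnorm(20)
    fitp <- fitLinear(Xp, yp)
    expect_equal(predict(fitp, Xp), yp, tolerance = 1e-8)
    # heavy ridge: coefficients collapse to zero, prediction to the mean
    fitr <- fitLinear(X, y, ridge = 1e12)
    expect_lt(max(abs(fitr$coefficients)), 1e-6)
    expect_equal(unname(predict(fitr, X[1:3, ])), rep(mean(y), 3),
                 tolerance = 1e-4)
    expect_error(fitLinear(rbind(c(1, NA), c(2, 3)), c(1, 2)), "non-finite")
})

test_that("forest fitting is seeded and finds the informative feature", {
    set.seed(2)
    # constant outcome: constant predictions
    Xc <- matrix(rnorm(30 * 4), 30, 4)
    fc <- fitForest(Xc, rep(5, 30), nTrees = 50, seed = 3)
    expect_equal(unname(predict(fc, Xc)), rep(5, 30))
    # same seed, identical predictions
    y <- rnorm(30)
    f1 <- fitForest(Xc, y, nTrees = 50, seed = 9)
    f2 <- fitForest(Xc, y, nTrees = 50, seed = 9)
    expect_identical(predict(f1, Xc), predict(f2, Xc))
    # 1 informative feature among 99 noise features
    n <- 300
    X <- matrix(rnorm(n * 100), n, 100)
    ys <- 3 * X[, 42] + rnorm(n, sd = 0.3)
    ff <- fitForest(X, ys, nTrees = 150, seed = 1)
    expect_equal(unname(which.max(ff$importance)), 42L)
})

test_that("metrics follow their definitions and degenerate rules", {
    expect_equal(unname(computeMetrics(c(1, 2, 3), c(1, 2, 3), 1)),
                 c(0, 1, 1))
    a <- c(3, 5, 9, 7)
    m <- computeMetrics(a, rep(mean(a), 4), 1)
    expect_equal(unname(m["r2"]), 0)
    expect_equal(unname(m["mse"]), mean((a - mean(a))^2))
    # adjusted formula: r2 = 0.5, n = 101, p = 1
    set.seed(3)
    aa <- rnorm(101); pp <- aa + rnorm(101)
    mm <- computeMetrics(aa, pp, 1)
    expect_equal(unname(mm["adj_r2"]),
                 1 - (1 - mm[["r2"]]) * 100 / 99)
    direct <- 1 - 0.5 * 100 / 99
    expect_equal(direct, 0.4949495, tolerance = 1e-6)
    # undefined adjusted R2 reported as NA with a message
    expect_message(m2 <- computeMetrics(c(1, 2, 3), c(1, 2, 2.5), 2),
                   "undefined")
    expect_true(is.na(m2["adj_r2"]))
    expect_error(computeMetrics(c(2, 2), c(1, 2), 1), "zero variance")
    # identities on random data: r2 <= 1, adj <= r2, mse = 0 <=> r2 = 1
    set.seed(4)
    for (i in 1:20) {
        n <- sample(10:60, 1)
        act <- rnorm(n, 40, 5); prd <- act + rnorm(n, sd = runif(1, 0, 6))
        p <- sample(1:4, 1)
        mt <- computeMetrics(act, prd, p)
        expect_lte(mt[["r2"]], 1)
        expect_lte(mt[["adj_r2"]], mt[["r2"]] + 1e-12)
        expect_identical(mt[["mse"]] == 0, mt[["r2"]] == 1)
    }
})

test_that("holdout evaluation splits 80/20 deterministically", {
    set.seed(5)
    X <- matrix(rnorm(1055 * 4), 1055, 4)
    y <- drop(X %*% c(1, 2, 0, -1)) + 40
    h <- holdoutEvaluate(X, y, "linear", splitFraction = 0.8, seed = 11)
    expect_equal(length(h$predicted), 1055 - floor(0.8 * 1055))
    expect_equal(length(h$testIndex), 211L)      # 1055 - 844
    expect_equal(unname(h$metrics["r2"]), 1, tolerance = 1e-9)
    expect_equal(unname(h$metrics["mse"]), 0, tolerance = 1e-12)
    h2 <- holdoutEvaluate(X, y, "linear", splitFraction = 0.8, seed = 11)
    expect_identical(h$metrics, h2$metrics)
    expect_identical(h$testIndex, h2$testIndex)
    expect_error(holdoutEvaluate(X[1:5, ], y[1:5], "linear",
                                 splitFraction = 0.9, seed = 1),
                 "smaller than 2")
})

test_that("k-fold CV partitions the data with balanced folds", {
    set.seed(6)
    n <- 103
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% c(1, -1, 2)) + rnorm(n, sd = 0.5) + 40
    cv <- kfoldCV(X, y, k = 10, modelKind = "linear", seed = 2)
    # test folds partition the index set with sizes differing by <= 1
    sizes <- table(cv$foldOf)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(sort(unique(cv$foldOf)), 1:10)
    # every sample has exactly one out-of-fold prediction
    expect_equal(length(cv$oof), n)
    expect_true(all(is.finite(cv$oof)))
    # means row equals the arithmetic fold means
    expect_equal(cv$means$mse, mean(cv$folds$mse))
    expect_equal(cv$means$r2, mean(cv$folds$r2))
    # leave-one-out: every test fold has one sample
    cvLoo <- kfoldCV(X[1:12, ], y[1:12], k = 12, modelKind = "linear",
                     seed = 1)
    expect_true(all(table(cvLoo$foldOf) == 1))
    expect_error(kfoldCV(X[1:5, ], y[1:5], k = 6, modelKind = "linear",
                         seed = 1), "exceeds")
})

test_that("fold summaries average the metric columns", {
    folds <- data.frame(mse = c(2, 4, 6), r2 = c(0.2, 0.4, 0.6),
                        adj_r2 = c(0.1, 0.3, 0.5))
    s <- summarizeFolds(folds)
    expect_equal(s$mse, 4); expect_equal(s$r2, 0.4)
    expect_equal(s$adj_r2, 0.3)
    same <- folds[c(2, 2, 2), ]
    expect_equal(summarizeFolds(same)$mse, 4)
})

test_that("forest importance ranks the signal feature and sums to 100", {
    set.seed(7)
    n <- 150
    X <- matrix(rnorm(n * 30), n, 30)
    X[, 5] <- X[, 5] * 2
    y <- 40 + 4 * X[, 5] + rnorm(n, sd = 0.8)
    cv <- kfoldCV(X, y, k = 5, modelKind = "forest", seed = 3, nTrees = 100)
    imp <- featureImportance(cv, X, y)
    expect_equal(sum(imp$importance_pct), 100, tolerance = 1e-6)
    expect_true(all(imp$importance_pct >= 0))
    expect_equal(imp$feature_index[1], 4L)        # 0-based index of col 5
    expect_gt(imp$correlation[1], 0.5)
    # negative association yields a negative correlation
    yNeg <- 40 - 4 * X[, 5] + rnorm(n, sd = 0.8)
    cvN <- kfoldCV(X, yNeg, k = 5, modelKind = "forest", seed = 3,
                   nTrees = 100)
    impN <- featureImportance(cvN, X, yNeg)
    expect_lt(impN$correlation[impN$feature_index == 4L], 0)
    # constant feature: correlation set to 0 with a note
    Xc <- X; Xc[, 2] <- 1
    cvC <- kfoldCV(Xc, y, k = 5, modelKind = "forest", seed = 3,
                   nTrees = 50)
    expect_message(impC <- featureImportance(cvC, Xc, y), "constant")
    expect_equal(impC$correlation[impC$feature_index == 1L], 0)
    # linear CV refuses importance extraction
    cvL <- kfoldCV(X, y, k = 5, modelKind = "linear", seed = 3)
    expect_error(featureImportance(cvL, X, y), "forest")
})

test_that("signed-error analysis ranks and thresholds out-of-fold misses", {
    ids <- c("29510124600", "29207470600", "t3", "t4")
    actual <- c(46.00, 39.80, 30.00, 41.00)
    predicted <- c(37.63, 48.32, 30.00, 44.00)
    ea <- errorAnalysis(ids, actual, predicted, thresholds = c(4, 2.5))
    rec <- ea$records
    expect_equal(rec$signed_error[rec$tract_id == "29510124600"], 8.37)
    expect_equal(rec$signed_error[rec$tract_id == "29207470600"], -8.52)
    expect_equal(rec$signed_error[rec$tract_id == "t3"], 0)
    # ranking is ascending in signed error
    expect_true(all(diff(rec$signed_error) >= 0))
    # thresholds: |error| >= 4 keeps the two large misses only
    expect_setequal(ea$subsets[["4"]]$tract_id,
                    c("29510124600", "29207470600"))
    # 2.5 additionally keeps the -3 miss; the exact tract never appears
    expect_setequal(ea$subsets[["2.5"]]$tract_id,
                    c("29510124600", "29207470600", "t4"))
    expect_false("t3" %in% ea$subsets[["2.5"]]$tract_id)
})
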