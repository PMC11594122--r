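# Regression of tract outcome rates on tract feature vectors: linear
# (minimum-norm / ridge) and random forest models, holdout and k-fold
# cross-validated evaluation, fold summaries, feature importance and
# signed-error analysis.

checkDesign <- function(X, y) {
    X <- as.matrix(X)
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("non-finite entries in the design matrix or outcome")
    if (nrow(X) != length(y)) stop("X and y disagree on n")
    if (nrow(X) < 2) stop("need at least 2 samples")
    X
}

#' Fit a linear (least-squares / ridge) regressor
#'
#' With \code{ridge = 0} returns the minimum-norm least-squares solution via
#' the singular-value pseudoinverse, which is well defined (and interpolates
#' the training data) even when the feature dimension exceeds the sample
#' size; \code{ridge > 0} gives the ridge solution. The intercept is never
#' penalized (features and outcome are centred internally). Deterministic.
#'
#' @param X n x D numeric matrix.
#' @param y numeric outcome vector (length n).
#' @param ridge non-negative ridge penalty.
#' @return An object of class \code{tsLinearModel} with elements
#'   \code{coefficients}, \code{intercept}, \code{rank}.
#' @export
fitLinear <- function(X, y, ridge = 0) {
    X <- checkDesign(X, y)
    stopifnot(ridge >= 0)
    xbar <- colMeans(X)
    ybar <- mean(y)
    Xc <- sweep(X, 2, xbar)
    sv <- svd(Xc)
    tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
    pos <- sv$d > tol
    shrink <- if (ridge == 0) ifelse(pos, 1 / sv$d, 0) else
        sv$d / (sv$d^2 + ridge)
    beta <- sv$v %*% (shrink * crossprod(sv$u, y - ybar))
    structure(list(coefficients = drop(beta),
                   intercept = ybar - sum(xbar * beta),
                   rank = sum(pos), ridge = ridge),
              class = "tsLinearModel")
}

#' @rdname fitLinear
#' @param object a fitted \code{tsLinearModel}.
#' @param newdata n x D matrix to predict for.
#' @param ... ignored.
#' @export
predict.tsLinearModel <- function(object, newdata, ...) {
    drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' Fit a seeded random forest regressor
#'
#' Bootstrap regression forest (via \pkg{ranger}) with impurity-based
#' per-feature importances; the same seed yields an identical model.
#'
#' @param X n x D numeric matrix.
#' @param y numeric outcome vector.
#' @param nTrees number of trees.
#' @param seed integer seed.
#' @param mtry features tried per split (default \code{floor(sqrt(D))}).
#' @return An object of class \code{tsForestModel}; impurity importances in
#'   \code{$importance}.
#' @export
fitForest <- function(X, y, nTrees = 500L, seed = 0L, mtry = NULL) {
    X <- checkDesign(X, y)
    if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)) - 1L)
    fit <- ranger::ranger(x = X, y = y, num.trees = nTrees,
                          importance = "impurity", seed = seed,
                          mtry = mtry, num.threads = 1L)
    structure(list(fit = fit, importance = fit$variable.importance,
                   featureNames = colnames(X)),
              class = "tsForestModel")
}

#' @rdname fitForest
#' @param object a fitted \code{tsForestModel}.
#' @param newdata n x D matrix to predict for.
#' @param ... ignored.
#' @export
predict.tsForestModel <- function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    colnames(newdata) <- object$featureNames
    stats::predict(object$fit, data = newdata,
                   num.threads = 1L)$predictions
}

fitModel <- function(X, y, modelKind, ridge = 0, nTrees = 500L, seed = 0L,
                     mtry = NULL) {
    switch(modelKind,
           linear = fitLinear(X, y, ridge = ridge),
           forest = fitForest(X, y, nTrees = nTrees, seed = seed,
                              mtry = mtry),
           stop("unknown model kind '", modelKind, "'"))
}

#' Regression evaluation metrics
#'
#' Mean squared error, coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and adjusted
#' \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)} for \code{pEff} effective
#' predictors. When \code{n <= pEff + 1} the adjusted value is undefined and
#' reported as NA (with a message).
#'
#' @param actual,predicted numeric vectors of equal length (n >= 2).
#' @param pEff effective predictor count (>= 1).
#' @return Named numeric: \code{mse}, \code{r2}, \code{adj_r2}.
#' @examples
#' computeMetrics(c(1, 2, 3), c(1, 2, 3), 1)
#' @export
computeMetrics <- function(actual, predicted, pEff) {
    n <- length(actual)
    stopifnot(length(predicted) == n, n >= 2, pEff >= 1)
    sst <- sum((actual - mean(actual))^2)
    if (sst == 0) stop("zero variance in actual values: R2 undefined")
    mse <- mean((actual - predicted)^2)
    r2 <- 1 - sum((actual - predicted)^2) / sst
    if (n <= pEff + 1) {
        message("adjusted R2 undefined: n = ", n, " <= pEff + 1 = ", pEff + 1)
        adj <- NA_real_
    } else adj <- 1 - (1 - r2) * (n - 1) / (n - pEff - 1)
    c(mse = mse, r2 = r2, adj_r2 = adj)
}

## Effective predictor count for adjusted R2 on an evaluation set.
## pEff = numeric: used as-is. pEff = "rank": training-design rank, capped so
## the adjusted-R2 denominator stays positive. The default of 1 treats the
## fitted model's prediction as a single derived predictor -- the convention
## under which per-fold adjusted values sit just below R2 even when the
## feature dimension exceeds the fold size (rank-based counts make the
## adjustment factor (n-1)/(n-p-1) degenerate on small test folds).
effectivePredictors <- function(Xtrain, nEval, pEff = 1L) {
    if (is.numeric(pEff)) return(as.integer(pEff))
    stopifnot(identical(pEff, "rank"))
    r <- qr(sweep(Xtrain, 2, colMeans(Xtrain)))$rank
    max(1L, min(r, nEval - 2L))
}

#' Holdout evaluation of a model
#'
#' Seeded random train/test split (training share \code{splitFraction},
#' \code{floor(splitFraction * n)} rows), fit on the training part, metrics
#' on the held-out part.
#'
#' @param X n x D matrix.
#' @param y outcome vector.
#' @param modelKind "linear" or "forest".
#' @param splitFraction training fraction in (0, 1) (default 0.8).
#' @param seed split (and forest) seed.
#' @param ridge,nTrees,mtry model parameters.
#' @param pEff effective predictors for adjusted R2: a number (default 1,
#'   the model prediction as one derived predictor) or "rank" for the
#'   training-design rank capped to keep the formula defined.
#' @return A list: \code{metrics} (mse, r2, adj_r2), \code{model},
#'   \code{testIndex}, \code{predicted} (held-out predictions), \code{pEff}.
#' @export
holdoutEvaluate <- function(X, y, modelKind = c("linear", "forest"),
                            splitFraction = 0.8, seed = 0L, ridge = 0,
                            nTrees = 500L, mtry = NULL, pEff = 1L) {
    modelKind <- match.arg(modelKind)
    X <- checkDesign(X, y)
    stopifnot(splitFraction > 0, splitFraction < 1)
    n <- nrow(X)
    nTrain <- floor(splitFraction * n)
    if (n - nTrain < 2) stop("test partition smaller than 2 samples")
    trainIdx <- withSeed(seed, sample.int(n, nTrain))
    testIdx <- setdiff(seq_len(n), trainIdx)
    model <- fitModel(X[trainIdx, , drop = FALSE], y[trainIdx], modelKind,
                      ridge = ridge, nTrees = nTrees, seed = seed,
                      mtry = mtry)
    pred <- predict(model, X[testIdx, , drop = FALSE])
    pEff <- effectivePredictors(X[trainIdx, , drop = FALSE],
                                length(testIdx), pEff)
    list(metrics = computeMetrics(y[testIdx], pred, pEff), model = model,
         testIndex = testIdx, predicted = pred, pEff = pEff)
}

#' k-fold cross-validation with pooled out-of-fold predictions
#'
#' Seeded shuffle, fold sizes differing by at most one, each sample tested
#' exactly once. Per-fold MSE, R2 and adjusted R2 plus the pooled
#' out-of-fold prediction for every sample.
#'
#' @param X n x D matrix.
#' @param y outcome vector.
#' @param k number of folds (2..n).
#' @param modelKind "linear" or "forest".
#' @param seed shuffle (and forest) seed.
#' @param ridge,nTrees,mtry model parameters.
#' @param pEff effective predictors for per-fold adjusted R2: a number
#'   (default 1) or "rank" (see [holdoutEvaluate()]).
#' @param keepModels keep the per-fold models (needed for
#'   [featureImportance()]).
#' @return An object of class \code{tsCVSummary}: \code{folds} (per-fold
#'   data.frame), \code{means} (fold-mean row from [summarizeFolds()]),
#'   \code{oof} (out-of-fold predictions, input order), \code{foldOf}
#'   (fold assignment), \code{models}.
#' @export
kfoldCV <- function(X, y, k = 10L, modelKind = c("linear", "forest"),
                    seed = 0L, ridge = 0, nTrees = 500L, mtry = NULL,
                    pEff = 1L, keepModels = TRUE) {
    modelKind <- match.arg(modelKind)
    X <- checkDesign(X, y)
    n <- nrow(X)
    if (k > n) stop("k = ", k, " exceeds the sample count n = ", n)
    stopifnot(k >= 2)
    perm <- withSeed(seed, sample.int(n))
    foldOf <- integer(n)
    foldOf[perm] <- rep(seq_len(k), length.out = n)
    oof <- numeric(n)
    models <- vector("list", k)
    folds <- vector("list", k)
    for (f in seq_len(k)) {
        testIdx <- which(foldOf == f)
        trainIdx <- which(foldOf != f)
        model <- fitModel(X[trainIdx, , drop = FALSE], y[trainIdx],
                          modelKind, ridge = ridge, nTrees = nTrees,
                          seed = seed + f, mtry = mtry)
        pred <- predict(model, X[testIdx, , drop = FALSE])
        oof[testIdx] <- pred
        pf <- effectivePredictors(X[trainIdx, , drop = FALSE],
                                  length(testIdx), pEff)
        # single-sample or zero-variance folds: MSE only, R2 undefined
        m <- if (length(testIdx) >= 2 &&
                 stats::var(y[testIdx]) > 0)
            computeMetrics(y[testIdx], pred, pf) else
            c(mse = mean((y[testIdx] - pred)^2), r2 = NA_real_,
              adj_r2 = NA_real_)
        folds[[f]] <- data.frame(fold = f, mse = m["mse"], r2 = m["r2"],
                                 adj_r2 = m["adj_r2"],
                                 n_test = length(testIdx), p_eff = pf,
                                 row.names = NULL)
        if (keepModels) models[[f]] <- model
    }
    folds <- do.call(rbind, folds)
    structure(list(folds = folds, means = summarizeFolds(folds), oof = oof,
                   foldOf = foldOf, models = models, modelKind = modelKind),
              class = "tsCVSummary")
}

#' @export
print.tsCVSummary <- function(x, ...) {
    cat("k-fold cross-validation (", x$modelKind, ", k = ",
        nrow(x$folds), ")\n", sep = "")
    print(x$folds[, c("fold", "mse", "r2", "adj_r2", "n_test")],
          row.names = FALSE, digits = 3)
    cat(sprintf("mean MSE %.2f | mean R2 %.3f | mean adjusted R2 %.3f\n",
                x$means$mse, x$means$r2, x$means$adj_r2))
    invisible(x)
}

#' Fold-mean summary row
#'
#' Arithmetic mean of each metric column over the folds.
#'
#' @param folds data.frame with columns \code{mse}, \code{r2}, \code{adj_r2}
#'   (one row per fold).
#' @return A one-row data.frame with the column means.
#' @export
summarizeFolds <- function(folds) {
    stopifnot(nrow(folds) >= 1)
    data.frame(mse = mean(folds$mse), r2 = mean(folds$r2),
               adj_r2 = mean(folds$adj_r2))
}

#' Forest feature importance with outcome correlations
#'
#' Averages the impurity importances over the cross-validation fold models,
#' rescales them to percentages summing to 100 and attaches each feature's
#' Pearson correlation with the actual outcome (or, optionally, with the
#' pooled out-of-fold predictions). Ranked by importance, descending.
#'
#' @param cv a \code{tsCVSummary} fitted with \code{modelKind = "forest"}
#'   and \code{keepModels = TRUE}.
#' @param X n x D design matrix used for the CV.
#' @param y actual outcome vector.
#' @param target correlate features with the "actual" outcome (default) or
#'   with the out-of-fold "predicted" values.
#' @return data.frame with \code{feature_index} (0-based), \code{feature},
#'   \code{importance_pct}, \code{correlation}.
#' @export
featureImportance <- function(cv, X, y, target = c("actual", "predicted")) {
    target <- match.arg(target)
    if (cv$modelKind != "forest" || is.null(cv$models[[1]]))
        stop("featureImportance needs the kept fold models of a forest CV")
    imp <- rowMeans(vapply(cv$models, function(m) m$importance,
                           numeric(ncol(X))))
    pct <- 100 * imp / sum(imp)
    ref <- if (target == "actual") y else cv$oof
    sds <- apply(X, 2, stats::sd)
    corr <- rep(0, ncol(X))
    ok <- sds > 0
    if (any(!ok))
        message(sum(!ok), " constant feature(s): correlation set to 0")
    corr[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok, drop = FALSE],
                                                      ref)))
    out <- data.frame(feature_index = seq_len(ncol(X)) - 1L,
                      feature = if (is.null(colnames(X)))
                          sprintf("f%04d", seq_len(ncol(X)) - 1L) else
                          colnames(X),
                      importance_pct = pct, correlation = corr,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$importance_pct), ]
    rownames(out) <- NULL
    out
}

#' Signed-error analysis of out-of-fold predictions
#'
#' Builds per-tract error records \code{signed_error = actual - predicted}
#' (positive: the model under-predicted the rate), ranks them, and for each
#' configured threshold emits the subset whose absolute error is at least
#' that threshold (the per-tract "RMSE" of a single out-of-fold prediction
#' is its absolute error).
#'
#' @param ids tract identifiers.
#' @param actual,predicted aligned rate vectors (%).
#' @param thresholds numeric error thresholds (default \code{c(4, 2.5)}).
#' @return A list: \code{records} (ranked by signed error, ascending) and
#'   \code{subsets} (one data.frame per threshold, named by threshold).
#' @export
errorAnalysis <- function(ids, actual, predicted, thresholds = c(4, 2.5)) {
    stopifnot(length(ids) == length(actual),
              length(actual) == length(predicted))
    rec <- data.frame(tract_id = as.character(ids), actual = actual,
                      predicted = predicted,
                      signed_error = actual - predicted,
                      stringsAsFactors = FALSE)
    rec <- rec[order(rec$signed_error), ]
    rownames(rec) <- NULL
    subsets <- lapply(thresholds, function(th)
        rec[abs(rec$signed_error) >= th, , drop = FALSE])
    names(subsets) <- as.character(thresholds)
    list(records = rec, subsets = subsets)
}
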