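#' Default hyperparameter grids
#'
#' Small exhaustive grids per model family: ridge penalties for logistic
#' regression; kernel x cost (x width for RBF) for the SVM; tree count x
#' depth cap for the random forest.
#'
#' @param family one of `"logistic"`, `"svm"`, `"rf"`.
#' @return data.frame, one row per hyperparameter combination.
#' @export
defaultGrid <- function(family = c("logistic", "svm", "rf")) {
  family <- match.arg(family)
  switch(family,
    logistic = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    svm = rbind(data.frame(kernel = "linear", cost = c(0.1, 1, 10)),
                data.frame(kernel = "radial", cost = c(0.1, 1, 10))),
    rf = expand.grid(ntree = c(200, 500), maxnodes = c(NA, 256)))
}

#' Fit a single classifier
#'
#' Standardises features on the given (training) data, fits the requested
#' model, and returns a self-contained fit usable by [predictScores()].
#' Scores are linear predictors (logistic), decision values (SVM) or class-1
#' vote fractions (random forest); the classification threshold is 0 for
#' the former two and 0.5 for the forest, i.e. the 0.5-probability rule.
#'
#' @param x features x samples training matrix.
#' @param y binary training labels.
#' @param family model family.
#' @param hyper one-row data.frame of hyperparameters (a [defaultGrid()]
#'   row); `NULL` for the family default.
#' @return object of class `ClassifierFit`.
#' @export
fitClassifier <- function(x, y, family = c("logistic", "svm", "rf"),
                          hyper = NULL) {
  family <- match.arg(family)
  y <- as_binary01(y)
  if (is.null(hyper)) hyper <- defaultGrid(family)[1, , drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- t((x - mu) / sd)                  # samples x features
  fit <- switch(family,
    logistic = cpp_ridge_logistic(Z, y, hyper$lambda, FALSE),
    svm = {
      args <- list(x = Z, y = factor(y, levels = c(0, 1)),
                   kernel = as.character(hyper$kernel), cost = hyper$cost,
                   scale = FALSE)
      do.call(e1071::svm, args)
    },
    rf = {
      args <- list(x = Z, y = factor(y, levels = c(0, 1)),
                   ntree = hyper$ntree)
      if (!is.na(hyper$maxnodes))
        args$maxnodes <- min(hyper$maxnodes, nrow(Z))
      do.call(randomForest::randomForest, args)
    })
  structure(list(family = family, fit = fit, center = mu, scale = sd,
                 hyper = hyper,
                 threshold = if (family == "rf") 0.5 else 0),
            class = "ClassifierFit")
}

#' Prediction scores of a fitted classifier
#'
#' @param object a `ClassifierFit`.
#' @param x features x samples matrix (same feature set as at fit time).
#' @return numeric score per sample (higher = more case-like).
#' @export
predictScores <- function(object, x) {
  Z <- t((x - object$center) / object$scale)
  switch(object$family,
    logistic = as.numeric(object$fit$beta[1] +
                          Z %*% object$fit$beta[-1]),
    svm = {
      pr <- stats::predict(object$fit, Z, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      ## e1071 orients the decision value by the first class seen; flip so
      ## higher always means class 1
      if (colnames(attr(pr, "decision.values"))[1] == "0/1") -dv else dv
    },
    rf = stats::predict(object$fit, Z, type = "prob")[, "1"])
}

#' Classification metrics at the 0.5-probability threshold
#'
#' @param scores numeric prediction scores.
#' @param y binary labels.
#' @param sex per-sample sex (`"F"`/`"M"`) for the sex-stratified
#'   accuracies; `NULL` yields NA for those.
#' @param threshold score cut-off for the hard prediction.
#' @return list of class `MetricSet`: auc, sensitivity, specificity,
#'   acc_female, acc_male, n.
#' @export
metricSet <- function(scores, y, sex = NULL, threshold = 0) {
  y <- as_binary01(y)
  pred <- as.integer(scores > threshold)
  sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
  spec <- if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
  accF <- accM <- NA_real_
  if (!is.null(sex)) {
    if (any(sex == "F")) accF <- mean((pred == y)[sex == "F"])
    if (any(sex == "M")) accM <- mean((pred == y)[sex == "M"])
  }
  structure(list(auc = rankAuc(scores, y), sensitivity = sens,
                 specificity = spec, acc_female = accF, acc_male = accM,
                 n = length(y)),
            class = "MetricSet")
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf(
    "MetricSet (n=%d): AUC %.3f | sens %.3f | spec %.3f | accF %.3f | accM %.3f\n",
    x$n, x$auc, x$sensitivity, x$specificity, x$acc_female, x$acc_male))
  invisible(x)
}

## stratified fold assignment: within each stratum shuffle and deal
## round-robin, so per-fold stratum counts differ by at most one
stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in split(seq_along(strata), strata)) {
    s <- s[sample.int(length(s))]
    fold[s] <- rep_len(seq_len(k), length(s))
  }
  fold
}

## inner grid search: stratified innerK-fold AUC per grid row, best row wins
tune_grid <- function(x, y, sex, family, grid, innerK = 3) {
  if (nrow(grid) == 1) return(grid[1, , drop = FALSE])
  strata <- if (is.null(sex)) factor(y) else interaction(y, sex, drop = TRUE)
  fold <- stratified_folds(strata, innerK)
  perf <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(innerK), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      fit <- fitClassifier(x[, tr, drop = FALSE], y[tr], family,
                           grid[gi, , drop = FALSE])
      rankAuc(predictScores(fit, x[, !tr, drop = FALSE]), y[!tr])
    }, numeric(1))
    perf[gi] <- mean(aucs, na.rm = TRUE)
  }
  grid[which.max(perf), , drop = FALSE]
}

#' Train on a matched set, evaluate once on a held-out set
#'
#' Hyperparameters are tuned by exhaustive grid search with nested
#' stratified cross-validation on the training data only; the model is then
#' refitted on all of the training set (standardisation included) and
#' evaluated a single time on the held-out samples.
#'
#' @param train,test lists with `x` (features x samples), `y` (labels) and
#'   optionally `sex` and `subject`; train and test must not share subjects.
#' @param family model family (see [fitClassifier()]).
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param innerK inner tuning folds.
#' @param seed RNG seed (fold assignment, forest fits).
#' @return a `MetricSet` with the fitted model attached as attribute
#'   `"fit"`.
#' @export
fitEvalHoldout <- function(train, test, family = "logistic", grid = NULL,
                           innerK = 3, seed = 1) {
  trSub <- if (!is.null(train$subject)) train$subject else colnames(train$x)
  teSub <- if (!is.null(test$subject)) test$subject else colnames(test$x)
  if (length(intersect(trSub, teSub)))
    stop("leakage: train and test share subjects")
  if (is.null(grid)) grid <- defaultGrid(family)
  set.seed(seed)
  best <- tune_grid(train$x, as_binary01(train$y), train$sex, family, grid,
                    innerK)
  fit <- fitClassifier(train$x, train$y, family, best)
  sc <- predictScores(fit, test$x)
  m <- metricSet(sc, test$y, test$sex, fit$threshold)
  attr(m, "fit") <- fit
  m
}

#' Repeated stratified cross-validated evaluation
#'
#' `nRepeats` repeats of stratified k-fold cross-validation (strata =
#' diagnosis x sex). Each outer training fold is tuned by nested stratified
#' grid search, refitted, and scored on its test fold; the summary is the
#' unweighted mean over all `nRepeats * k` folds, and the per-fold AUC
#' vector is retained for paired model comparison.
#'
#' @param data list with `x` (features x samples), `y`, `sex`.
#' @param family model family.
#' @param nRepeats,k repeats and folds (protocol default 50 x 5).
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @param innerK inner tuning folds.
#' @param seed RNG seed controlling the fold sequence.
#' @return list of class `CvResult`: `summary` (a `MetricSet`-like list of
#'   fold means), `folds` (per-fold data.frame), `foldAucs`.
#' @export
repeatedCvEval <- function(data, family = "logistic", nRepeats = 50, k = 5,
                           grid = NULL, innerK = 3, seed = 1) {
  y <- as_binary01(data$y)
  sex <- data$sex
  strata <- if (is.null(sex)) factor(y) else interaction(y, sex, drop = TRUE)
  if (min(table(strata)) < k)
    stop("a diagnosis x sex stratum is smaller than k")
  if (is.null(grid)) grid <- defaultGrid(family)
  set.seed(seed)
  rows <- list()
  for (r in seq_len(nRepeats)) {
    fold <- stratified_folds(strata, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      best <- tune_grid(data$x[, tr, drop = FALSE], y[tr], sex[tr], family,
                        grid, innerK)
      fit <- fitClassifier(data$x[, tr, drop = FALSE], y[tr], family, best)
      sc <- predictScores(fit, data$x[, !tr, drop = FALSE])
      m <- metricSet(sc, y[!tr], if (is.null(sex)) NULL else sex[!tr],
                     fit$threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, auc = m$auc,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   acc_female = m$acc_female, acc_male = m$acc_male)
    }
  }
  folds <- do.call(rbind, rows)
  summary <- lapply(folds[, c("auc", "sensitivity", "specificity",
                              "acc_female", "acc_male")],
                    mean, na.rm = TRUE)
  structure(list(summary = summary, folds = folds, foldAucs = folds$auc,
                 family = family, nRepeats = nRepeats, k = k),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult (%s, %dx%d folds): mean AUC %.3f\n", x$family,
              x$nRepeats, x$k, x$summary$auc))
  invisible(x)
}

#' Concatenate feature blocks
#'
#' Column-binds named feature blocks (samples in rows) sharing an identical
#' sample-id set, prefixing feature names with the block name. Per-feature
#' scaling is left to the model pipeline so that it is always computed on
#' training folds only.
#'
#' @param blocks named list of samples x features matrices/data.frames with
#'   sample ids as rownames.
#' @return fused samples x features matrix.
#' @export
fuseBlocks <- function(blocks) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be named")
  ids <- rownames(blocks[[1]])
  for (b in blocks)
    if (!setequal(rownames(b), ids))
      stop("blocks must share an identical sample-id set")
  fused <- do.call(cbind, lapply(names(blocks), function(nm) {
    m <- as.matrix(blocks[[nm]])[ids, , drop = FALSE]
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  }))
  rownames(fused) <- ids
  fused
}

#' Paired comparison of per-fold AUCs
#'
#' Two-sided Wilcoxon signed-rank on the paired per-fold differences of two
#' models evaluated under the same fold sequence; zero differences are
#' dropped per the standard convention, and an all-zero difference vector
#' is reported as p = 1.
#'
#' @param a,b numeric per-fold AUC vectors of equal length.
#' @return list with statistic, p.value and meanDiff.
#' @export
compareFoldAucs <- function(a, b) {
  if (length(a) != length(b)) stop("fold vectors differ in length")
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, meanDiff = 0))
  wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       meanDiff = mean(d))
}

#' Sampled-permutation Shapley importance
#'
#' Model-agnostic Shapley estimate: for each test sample, feature
#' contributions are marginal score changes averaged over random feature
#' orderings, walking from a baseline (training-set feature means) to the
#' observed vector. Importance is the mean absolute value over all test
#' predictions; for additive models the per-prediction values plus the
#' baseline score reconstruct the model score.
#'
#' @param fit a `ClassifierFit`.
#' @param testX features x samples matrix.
#' @param nPermutations random orderings per sample.
#' @param seed RNG seed.
#' @param baseline baseline feature vector (default the training means
#'   stored in the fit).
#' @return list of class `ImportanceResult`: `values` (features x samples
#'   mean contributions), `importance` (sorted mean |value|), `baseScore`.
#' @export
shapleyImportance <- function(fit, testX, nPermutations = 100, seed = 1,
                              baseline = fit$center) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  set.seed(seed)
  p <- nrow(testX); nT <- ncol(testX)
  feats <- rownames(testX)
  vals <- matrix(0, p, nT, dimnames = list(feats, colnames(testX)))
  baseScore <- predictScores(fit, matrix(baseline, ncol = 1,
                                         dimnames = list(feats, "base")))
  for (s in seq_len(nT)) {
    xs <- testX[, s]
    acc <- numeric(p)
    for (perm in seq_len(nPermutations)) {
      ord <- sample.int(p)
      ## path of p+1 points from baseline to the observed sample
      path <- matrix(baseline, p, p + 1, dimnames = list(feats, NULL))
      for (j in seq_len(p))
        path[ord[seq_len(j)], j + 1] <- xs[ord[seq_len(j)]]
      sc <- predictScores(fit, path)
      acc[ord] <- acc[ord] + diff(sc)
    }
    vals[, s] <- acc / nPermutations
  }
  imp <- sort(rowMeans(abs(vals)), decreasing = TRUE)
  structure(list(values = vals, importance = imp,
                 baseScore = unname(baseScore)),
            class = "ImportanceResult")
}

#' @export
print.ImportanceResult <- function(x, ...) {
  cat("ImportanceResult:", nrow(x$values), "features,", ncol(x$values),
      "predictions\n top:",
      paste(utils::head(names(x$importance), 5), collapse = ", "), "\n")
  invisible(x)
}
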