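## F-statistic relevance of each feature (row) for a binary label; constant
## features get relevance 0.
f_relevance <- function(matrix, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  m1 <- rowMeans(matrix[, y == 1, drop = FALSE])
  m0 <- rowMeans(matrix[, y == 0, drop = FALSE])
  ss1 <- rowSums((matrix[, y == 1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((matrix[, y == 0, drop = FALSE] - m0)^2)
  sp2 <- (ss1 + ss0) / (n - 2)
  f <- (m1 - m0)^2 / (sp2 * (1 / n1 + 1 / n0))
  f[!is.finite(f)] <- 0
  f
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance ordering for continuous features and
#' a binary label: relevance is the one-way F statistic of feature versus
#' label, redundancy the mean absolute Pearson correlation with the features
#' already selected (floored at 1e-6), combined by the quotient scheme
#' (relevance / redundancy; the difference scheme is available). The first
#' feature is the relevance maximum; ties break lexically by feature id, so
#' the ordering is deterministic.
#'
#' @param matrix features x samples matrix.
#' @param labels binary labels.
#' @param listLength how many features to rank (default 500, capped at the
#'   feature count).
#' @param scheme `"quotient"` (default) or `"difference"`.
#' @return character vector of feature ids, best first.
#' @export
mrmrRank <- function(matrix, labels, listLength = 500,
                     scheme = c("quotient", "difference")) {
  scheme <- match.arg(scheme)
  y <- as_binary01(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  if (nrow(matrix) < 2) stop("need at least 2 features")
  L <- min(listLength, nrow(matrix))
  feats <- rownames(matrix)
  rel <- f_relevance(matrix, y)
  if (all(rel == 0)) stop("all features are constant")
  n <- ncol(matrix)

  ## row-standardised copy for fast correlations; constant rows become zero
  mu <- rowMeans(matrix)
  sd <- sqrt(rowSums((matrix - mu)^2) / (n - 1))
  Z <- (matrix - mu) / ifelse(sd > 0, sd, Inf)

  selected <- character(L)
  absCorSum <- numeric(nrow(matrix))
  remaining <- rep(TRUE, nrow(matrix))
  ## first pick: max relevance, lexical tie-break
  first <- order(-rel, feats)[1]
  selected[1] <- feats[first]
  remaining[first] <- FALSE
  last <- first
  for (k in seq_len(L - 1)) {
    absCorSum <- absCorSum + abs(as.numeric(Z %*% Z[last, ]) / (n - 1))
    red <- pmax(absCorSum / k, 1e-6)
    score <- if (scheme == "quotient") rel / red else rel - red
    score[!remaining] <- -Inf
    nxt <- order(-score, feats)[1]
    selected[k + 1] <- feats[nxt]
    remaining[nxt] <- FALSE
    last <- nxt
  }
  selected
}

## stratified index subsample (proportion per stratum, floor, at least 1)
stratified_subsample <- function(strata, prop) {
  unlist(lapply(split(seq_along(strata), strata), function(idx) {
    if (length(idx) < 2) stop("stratum of size < 2; cannot subsample")
    k <- max(1L, floor(prop * length(idx)))
    idx[sample.int(length(idx), k)]
  }), use.names = FALSE)
}

#' Ensemble mRMR ranking over stratified subsamples
#'
#' Runs [mrmrRank()] on repeated 80% subsamples stratified by diagnosis and
#' sex. A feature at position p of a length-L list scores `L + 1 - p` for
#' that list and 0 when it is absent from the list; the final score is the
#' mean over all repeats, ordered descending with lexical tie-break.
#'
#' @param matrix features x samples matrix.
#' @param labels binary diagnosis labels.
#' @param sex per-sample sex labels (second stratification factor).
#' @param nRepeats number of subsampled runs (protocol default 50).
#' @param subsample subsampled fraction per stratum (default 0.8).
#' @param listLength ranked-list length L (protocol default 500).
#' @param seed integer RNG seed.
#' @param scheme passed to [mrmrRank()].
#' @return a [FeatureRanking-class].
#' @export
ensembleRank <- function(matrix, labels, sex, nRepeats = 50,
                         subsample = 0.8, listLength = 500, seed = 1,
                         scheme = "quotient") {
  y <- as_binary01(labels)
  strata <- interaction(y, sex, drop = TRUE)
  set.seed(seed)
  L <- min(listLength, nrow(matrix))
  lists <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    idx <- if (subsample >= 1) seq_len(ncol(matrix))
           else stratified_subsample(strata, subsample)
    lists[[r]] <- mrmrRank(matrix[, idx, drop = FALSE], y[idx],
                           listLength = L, scheme = scheme)
  }
  aggregate_rank_lists(lists, rownames(matrix), L)
}

## position p in a length-L list scores L+1-p; absent from a list scores 0;
## final score = mean over lists, descending order with lexical tie-break
aggregate_rank_lists <- function(lists, feats, L) {
  scoreMat <- vapply(lists, function(l) {
    s <- numeric(length(feats)); names(s) <- feats
    s[l] <- L + 1 - seq_along(l)
    s
  }, numeric(length(feats)))
  if (is.null(dim(scoreMat)))
    scoreMat <- matrix(scoreMat, ncol = length(lists))
  meanScore <- rowMeans(scoreMat)
  names(meanScore) <- feats
  ord <- order(-meanScore, feats)
  new("FeatureRanking", scores = meanScore[ord], perRepeat = lists,
      listLength = L)
}

#' Scan classifier performance over feature counts
#'
#' Trains each classifier on the top-c features of the aggregated ranking
#' for every count c on the grid (default 50 to 500 in steps of 10) and
#' records the holdout AUC. Standardisation and fitting use the training
#' set only; train and holdout must not share subjects.
#'
#' @param train,holdout lists with elements `x` (features x samples matrix),
#'   `y` (binary labels) and optionally `subject` (ids for the leakage
#'   check; defaults to column names).
#' @param ranking a [FeatureRanking-class].
#' @param grid increasing feature counts to evaluate.
#' @param classifiers subset of `c("logistic", "svm", "rf")`.
#' @param seed RNG seed (random-forest fits).
#' @return list of class `ScanResult`: `grid`, `auc` (counts x classifiers
#'   matrix) and the ranked feature order used.
#' @export
scanFeatureCounts <- function(train, holdout, ranking,
                              grid = seq(50, 500, 10),
                              classifiers = "logistic", seed = 1) {
  trSub <- if (!is.null(train$subject)) train$subject else colnames(train$x)
  hoSub <- if (!is.null(holdout$subject)) holdout$subject
           else colnames(holdout$x)
  if (length(intersect(trSub, hoSub)))
    stop("leakage: train and holdout share subjects")
  ordFeat <- names(rankScores(ranking))
  if (max(grid) > length(ordFeat))
    stop("grid exceeds the number of ranked features")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  auc <- matrix(NA_real_, length(grid), length(classifiers),
                dimnames = list(as.character(grid), classifiers))
  set.seed(seed)
  for (cl in classifiers) {
    for (gi in seq_along(grid)) {
      fs <- ordFeat[seq_len(grid[gi])]
      fit <- fitClassifier(train$x[fs, , drop = FALSE], train$y, family = cl)
      sc <- predictScores(fit, holdout$x[fs, , drop = FALSE])
      auc[gi, cl] <- rankAuc(sc, holdout$y)
    }
  }
  structure(list(grid = grid, auc = auc, featureOrder = ordFeat),
            class = "ScanResult")
}

#' Select the best feature subset under a size cap
#'
#' Restricts the scan grid to counts of at most `maxFeatures`, picks the
#' count with the highest holdout AUC per classifier, and resolves AUC ties
#' in favour of the smallest count.
#'
#' @param scan a `ScanResult` from [scanFeatureCounts()].
#' @param maxFeatures size cap (protocol default 200).
#' @return named list per classifier: `count`, `auc`, `features`.
#' @export
selectBestSubset <- function(scan, maxFeatures = 200) {
  ok <- scan$grid <= maxFeatures
  if (!any(ok)) stop("no grid entry satisfies the feature cap")
  out <- lapply(colnames(scan$auc), function(cl) {
    a <- scan$auc[ok, cl]
    g <- scan$grid[ok]
    best <- g[order(-a, g)][1]
    list(count = best, auc = a[match(best, g)],
         features = scan$featureOrder[seq_len(best)])
  })
  names(out) <- colnames(scan$auc)
  out
}
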