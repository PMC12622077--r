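#' Rank-based AUC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor; the
#'   second level / 1 / TRUE is the positive class).
#' @return AUC in `[0,1]`.
#' @export
rankAuc <- function(scores, labels) {
  y <- as_binary01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary01 <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) > 2) stop("labels must be binary")
    labels <- as.integer(labels == lev[length(lev)])
    ## "AD"/"CTL": make the disease class positive
    if (identical(lev, c("AD", "CTL"))) labels <- 1L - labels
  }
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  y
}

#' Sample random gene sets
#'
#' Draws `nIterations` feature sets of size `setSize`, each uniformly without
#' replacement from the feature universe, independently across iterations and
#' reproducibly from the seed. The returned manifest can be replayed on
#' another variant of the same dataset for paired comparison.
#'
#' @param featureIds feature universe.
#' @param setSize features per set (default 75).
#' @param nIterations number of sets (default 10000).
#' @param seed integer RNG seed.
#' @return list of character vectors.
#' @export
sampleGeneSets <- function(featureIds, setSize = 75, nIterations = 10000,
                           seed = 1) {
  if (setSize > length(featureIds))
    stop("setSize exceeds the feature universe")
  set.seed(seed)
  lapply(seq_len(nIterations), function(i) sample(featureIds, setSize))
}

#' Leave-one-out cross-validated AUC
#'
#' For each sample, an L2-regularised logistic regression (summed log-loss
#' plus `0.5 * lambda * ||w||^2`, intercept unpenalised, features
#' standardised on the training fold) is fitted on the remaining samples and
#' the held-out linear predictor recorded; the pooled n out-of-fold scores
#' are summarised by a single rank-based AUC.
#'
#' @param matrixSubset features x samples matrix (the candidate gene set).
#' @param labels binary diagnosis labels.
#' @param lambda ridge penalty (default 1, the common library default).
#' @param standardize standardise features within each training fold.
#' @return list with `auc` and the per-sample out-of-fold `scores`.
#' @export
loocvAuc <- function(matrixSubset, labels, lambda = 1, standardize = TRUE) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  if (ncol(matrixSubset) < 3) stop("need at least 3 samples for LOOCV")
  scores <- cpp_loocv_ridge_logistic(t(matrixSubset), y, lambda, standardize)
  list(auc = rankAuc(scores, y), scores = as.numeric(scores))
}

#' Random-gene-set bias audit
#'
#' Measures dataset-level systematic bias as the classification performance
#' of gene sets sampled at random: each iteration draws `setSize` features
#' (or replays a supplied manifest), trains a logistic regression under
#' leave-one-out cross-validation and records the pooled out-of-fold AUC.
#' On an unbiased dataset the mean AUC sits at 0.5; batch structure or
#' composition shifts associated with diagnosis inflate it.
#'
#' @param matrix features x samples log2 expression matrix.
#' @param labels binary diagnosis labels, one per sample.
#' @param nIterations sets to draw (protocol default 10000).
#' @param setSize features per set (protocol default 75).
#' @param seed integer RNG seed for set sampling.
#' @param manifest optional list of feature-id sets to replay instead of
#'   sampling (for paired comparisons across dataset variants).
#' @param lambda ridge penalty of the audit classifier.
#' @return an [AuditResult-class].
#' @export
runAudit <- function(matrix, labels, nIterations = 10000, setSize = 75,
                     seed = 1, manifest = NULL, lambda = 1) {
  if (is.null(manifest)) {
    manifest <- sampleGeneSets(rownames(matrix), setSize, nIterations, seed)
  } else {
    missing <- setdiff(unique(unlist(manifest)), rownames(matrix))
    if (length(missing))
      stop("manifest features absent from matrix: ",
           paste(utils::head(missing, 3), collapse = ", "))
    nIterations <- length(manifest)
  }
  y <- as_binary01(labels)
  aucs <- vapply(manifest, function(gs)
    loocvAuc(matrix[gs, , drop = FALSE], y, lambda = lambda)$auc,
    numeric(1))
  new("AuditResult", aucs = aucs, manifest = manifest,
      config = list(nIterations = nIterations, setSize = setSize,
                    seed = seed, lambda = lambda,
                    classifier = "ridge-logistic LOOCV"))
}

#' Compare two audit results
#'
#' Paired Wilcoxon signed-rank on per-iteration AUC differences when both
#' audits used the same gene-set manifest; otherwise a two-sided rank-sum
#' test. When every paired difference is zero the p-value is reported as 1
#' by convention.
#'
#' @param a,b [AuditResult-class] objects.
#' @param paired force/forbid pairing; default `NULL` pairs iff the
#'   manifests are identical.
#' @return list with statistic, p.value, meanDiff (`mean(a) - mean(b)`),
#'   per-arm mean and sd, and the method used.
#' @export
compareAudits <- function(a, b, paired = NULL) {
  sameManifest <- identical(setManifest(a), setManifest(b))
  if (is.null(paired)) paired <- sameManifest
  if (paired && !sameManifest)
    stop("paired comparison requires identical gene-set manifests")
  x <- aucValues(a); yv <- aucValues(b)
  if (paired) {
    d <- x - yv
    if (all(d == 0)) {
      stat <- 0; p <- 1; method <- "paired Wilcoxon signed-rank"
    } else {
      wt <- stats::wilcox.test(x, yv, paired = TRUE, exact = FALSE)
      stat <- unname(wt$statistic); p <- wt$p.value; method <- wt$method
    }
  } else {
    wt <- stats::wilcox.test(x, yv, exact = FALSE)
    stat <- unname(wt$statistic); p <- wt$p.value; method <- wt$method
  }
  list(statistic = stat, p.value = p, meanDiff = mean(x) - mean(yv),
       mean_a = mean(x), sd_a = stats::sd(x),
       mean_b = mean(yv), sd_b = stats::sd(yv), method = method)
}

#' Technical-replicate concordance
#'
#' Mean pairwise Pearson correlation (across features) within replicate
#' groups versus between unrelated samples. Within-replicate concordance
#' exceeding the between-sample value bounds the platform's technical noise
#' below the biological signal.
#'
#' @param matrix features x samples matrix.
#' @param metadata per-sample data.frame with a `replicate_group` column
#'   (NA for unreplicated samples), rows aligned with `colnames(matrix)`.
#' @return list with `within`, `between` (mean correlations), their sds and
#'   pair counts.
#' @export
replicateConcordance <- function(matrix, metadata) {
  grp <- metadata$replicate_group
  if (is.null(grp) || !any(!is.na(grp) & duplicated(grp) |
                           !is.na(grp) & rev(duplicated(rev(grp)))))
    stop("no replicate groups of size >= 2 in metadata")
  cc <- stats::cor(matrix)
  n <- ncol(matrix)
  same <- outer(grp, grp, function(a, b) !is.na(a) & !is.na(b) & a == b)
  ut <- upper.tri(cc)
  within <- cc[ut & same]
  between <- cc[ut & !same]
  if (!length(within)) stop("no replicate pairs found")
  list(within = mean(within), between = mean(between),
       within_sd = stats::sd(within), between_sd = stats::sd(between),
       n_within_pairs = length(within), n_between_pairs = length(between))
}
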