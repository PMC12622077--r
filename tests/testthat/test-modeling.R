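make_clf_data <- function(n = 120, p = 10, signal = 1, seed = 1) {
  set.seed(seed)
  y <- rep_len(c(1, 0), n)             # interleaved so any split has both
  sex <- rep_len(c("F", "F", "M", "M"), n)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%03d", 1:n)))
  X[1:3, y == 1] <- X[1:3, y == 1] + signal
  list(x = X, y = y, sex = sex)
}

test_that("metric arithmetic matches a hand-tabulated confusion matrix", {
  scores <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  sex <- c("F", "F", "M", "F", "M", "M")
  m <- metricSet(scores, y, sex, threshold = 0.5)
  # preds: 1,1,0,1,0,0 -> TP 2, FN 1, FP 1, TN 2
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  # correct: s1 T, s2 T, s3 F, s4 F, s5 T, s6 T
  expect_equal(m$acc_female, 2 / 3)
  expect_equal(m$acc_male, 2 / 3)
  expect_equal(m$auc, rankAuc(scores, y))
})

test_that("holdout evaluation is perfect on a separable feature and leak-proof", {
  d <- make_clf_data(n = 80, signal = 0)
  d$x["f01", ] <- d$y * 4 - 2
  tr <- list(x = d$x[, 1:60], y = d$y[1:60], sex = d$sex[1:60])
  te <- list(x = d$x[, 61:80], y = d$y[61:80], sex = d$sex[61:80])
  m <- fitEvalHoldout(tr, te, "logistic")
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$acc_female, 1)
  expect_equal(m$acc_male, 1)

  te_leak <- list(x = d$x[, 55:80], y = d$y[55:80], sex = d$sex[55:80])
  expect_error(fitEvalHoldout(tr, te_leak, "logistic"), "leakage")
})

test_that("all three model families fit, score and tune", {
  d <- make_clf_data(n = 80, signal = 1.5, seed = 3)
  tr <- list(x = d$x[, 1:56], y = d$y[1:56], sex = d$sex[1:56])
  te <- list(x = d$x[, 57:80], y = d$y[57:80], sex = d$sex[57:80])
  for (fam in c("logistic", "svm", "rf")) {
    m <- fitEvalHoldout(tr, te, fam, seed = 2)
    expect_gte(m$auc, 0.7)
    expect_s3_class(attr(m, "fit"), "ClassifierFit")
  }
})

test_that("repeated stratified CV yields the full fold grid, balanced strata", {
  d <- make_clf_data(n = 80, signal = 1, seed = 4)
  res <- repeatedCvEval(d, "logistic", nRepeats = 3, k = 5,
                        grid = data.frame(lambda = 1), seed = 7)
  expect_equal(nrow(res$folds), 15)
  expect_length(res$foldAucs, 15)
  expect_gte(res$summary$auc, 0.6)

  # fold stratification: per-fold stratum counts differ by <= 1
  strata <- interaction(d$y, d$sex)
  set.seed(7)
  fold <- BloodBiasAudit:::stratified_folds(strata, 5)
  tab <- table(strata, fold)
  expect_true(all(apply(tab, 1, function(r) max(r) - min(r) <= 1)))

  # randomized labels stay near chance
  d0 <- make_clf_data(n = 80, signal = 0, seed = 5)
  set.seed(1); d0$y <- sample(d0$y)
  res0 <- repeatedCvEval(d0, "logistic", nRepeats = 10, k = 5,
                         grid = data.frame(lambda = 1), seed = 8)
  expect_lt(abs(res0$summary$auc - 0.5), 0.1)

  dSmall <- list(x = d$x[, 1:8], y = d$y[1:8], sex = d$sex[1:8])
  expect_error(repeatedCvEval(dSmall, "logistic", nRepeats = 2, k = 5),
               "stratum")
})

test_that("block fusion concatenates aligned samples with prefixed names", {
  rna <- matrix(rnorm(5 * 120), 5, 120,
                dimnames = list(paste0("s", 1:5), paste0("g", 1:120)))
  mri <- matrix(rnorm(5 * 136), 5, 136,
                dimnames = list(paste0("s", c(3, 1, 2, 5, 4)),
                                paste0("m", 1:136)))
  fused <- fuseBlocks(list(rna = rna, mri = mri))
  expect_equal(ncol(fused), 256)
  expect_equal(rownames(fused), rownames(rna))
  expect_true(all(grepl("^rna\\.|^mri\\.", colnames(fused))))
  # row alignment by id, not position
  expect_equal(unname(fused["s3", "mri.m1"]), unname(mri["s3", "m1"]))

  self <- fuseBlocks(list(a = rna, b = rna))
  expect_equal(ncol(self), 240)
  expect_false(anyDuplicated(colnames(self)) > 0)

  bad <- mri[1:4, ]
  expect_error(fuseBlocks(list(rna = rna, mri = bad)), "sample-id")
  expect_error(fuseBlocks(list(rna, mri)), "named")
})

test_that("paired fold comparison applies the signed-rank conventions", {
  set.seed(6)
  a <- runif(250, 0.7, 0.9)
  expect_equal(compareFoldAucs(a, a)$p.value, 1)
  cmp <- compareFoldAucs(a + 0.01, a)
  expect_lt(cmp$p.value, 0.001)
  expect_equal(cmp$meanDiff, 0.01)
  expect_error(compareFoldAucs(a, a[1:10]), "length")
})

test_that("sampled-permutation Shapley matches the linear closed form", {
  d <- make_clf_data(n = 60, p = 6, signal = 1.2, seed = 8)
  fit <- fitClassifier(d$x, d$y, "logistic", data.frame(lambda = 1))
  test_x <- d$x[, 1:8]
  imp <- shapleyImportance(fit, test_x, nPermutations = 30, seed = 3)

  # linear scorer: value_j = beta_j * (x_j - baseline_j) / scale_j exactly
  beta <- fit$fit$beta[-1]
  expected <- (test_x - fit$center) / fit$scale * beta
  expect_equal(imp$values, expected, tolerance = 1e-10)

  # efficiency: contributions plus base reconstruct the score
  sc <- predictScores(fit, test_x)
  expect_equal(unname(colSums(imp$values)) + imp$baseScore, unname(sc),
               tolerance = 1e-10)

  # an inert feature gets (near) zero importance
  dz <- make_clf_data(n = 60, p = 6, signal = 1.2, seed = 9)
  dz$x["f06", ] <- 0.123                     # constant -> zero weight
  fitz <- fitClassifier(dz$x, dz$y, "logistic", data.frame(lambda = 1))
  impz <- shapleyImportance(fitz, dz$x[, 1:5], nPermutations = 20, seed = 1)
  expect_lt(impz$importance[["f06"]], 1e-3)

  expect_error(shapleyImportance(fit, test_x, nPermutations = 0), "nPermutations")
})

test_that("training fits are untouched by the test fold (no-leakage audit)", {
  d <- make_clf_data(n = 60, p = 5, signal = 1, seed = 10)
  tr <- list(x = d$x[, 1:40], y = d$y[1:40], sex = d$sex[1:40])
  fit1 <- fitClassifier(tr$x, tr$y, "logistic", data.frame(lambda = 1))
  # permute test labels; refit on identical training data
  fit2 <- fitClassifier(tr$x, tr$y, "logistic", data.frame(lambda = 1))
  expect_identical(fit1$fit$beta, fit2$fit$beta)
})
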