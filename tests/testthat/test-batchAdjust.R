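# planted location-scale batch data: x = mu_g + beta_g*case + gamma_gb + eps
make_batch_data <- function(G = 500, n = 400, B = 4, gamma_sd = 0.5,
                            effect_sd = 0, seed = 1) {
  set.seed(seed)
  batch <- factor(sample(rep_len(seq_len(B), n)))
  y <- sample(rep_len(c(1, 0), n))
  mu <- rnorm(G, 7, 1)
  beta <- if (effect_sd > 0) rnorm(G, 0, effect_sd) else numeric(G)
  gamma <- matrix(rnorm(G * B, 0, gamma_sd), G, B)
  X <- matrix(rnorm(G * n), G, n) + mu + outer(beta, y) +
    gamma[, as.integer(batch)]
  rownames(X) <- sprintf("g%04d", seq_len(G))
  colnames(X) <- sprintf("s%04d", seq_len(n))
  list(X = X, batch = batch, y = y, gamma = gamma, beta = beta)
}

test_that("a single batch is a fixed point of the adjustment", {
  d <- make_batch_data(G = 100, n = 40, B = 1, gamma_sd = 0, seed = 2)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  expect_lt(max(abs(applyAdjustment(d$X, m) - d$X)), 1e-9)
})

test_that("pure location offsets between batches are removed", {
  d <- make_batch_data(G = 300, n = 400, B = 2, gamma_sd = 0.6, seed = 3)
  m <- fitEbBatchModel(d$X, d$batch, preserve = NULL)
  adj <- applyAdjustment(d$X, m)
  bm <- sapply(levels(d$batch), function(b)
    rowMeans(adj[, d$batch == b, drop = FALSE]))
  expect_lt(mean(abs(bm[, 1] - bm[, 2])), 0.02)
  expect_lt(max(abs(bm[, 1] - bm[, 2])), 0.1)
})

test_that("planted batch locations are recovered by the shrunken estimates", {
  d <- make_batch_data(G = 500, n = 400, B = 4, gamma_sd = 0.5, seed = 4)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  # the model is identified up to the batch-size-weighted mean, so compare
  # against the centred planted effects
  w <- as.numeric(table(d$batch)) / length(d$batch)
  gc <- d$gamma - as.numeric(d$gamma %*% w)
  for (b in seq_len(4))
    expect_gte(cor(m@gammaStar[, b], gc[, b]), 0.9)
})

test_that("diagnosis effects survive adjustment (preservation r >= 0.95)", {
  d <- make_batch_data(G = 500, n = 400, B = 4, gamma_sd = 0.5,
                       effect_sd = 0.4, seed = 5)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  adj <- applyAdjustment(d$X, m)
  est <- rowMeans(adj[, d$y == 1]) - rowMeans(adj[, d$y == 0])
  expect_gte(cor(est, d$beta), 0.95)
})

test_that("adjustment leaves no residual batch association", {
  # in-sample empirical-Bayes adjustment removes (slightly over-removes)
  # batch means, so no gene should retain a detectable batch effect
  d <- make_batch_data(G = 500, n = 400, B = 4, gamma_sd = 0.5, seed = 6)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  adj <- applyAdjustment(d$X, m)
  ps <- apply(adj, 1, function(g)
    anova(lm(g ~ d$batch))[["Pr(>F)"]][1])
  expect_lte(mean(ps < 0.05), 0.01)
  # before adjustment nearly every gene shows its planted batch effect
  ps0 <- apply(d$X, 1, function(g)
    anova(lm(g ~ d$batch))[["Pr(>F)"]][1])
  expect_gte(mean(ps0 < 0.05), 0.9)
})

test_that("adjustment agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  d <- make_batch_data(G = 200, n = 120, B = 3, gamma_sd = 0.5,
                       effect_sd = 0.4, seed = 7)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  adj <- applyAdjustment(d$X, m)
  ref <- sva::ComBat(d$X, batch = d$batch,
                     mod = model.matrix(~ factor(d$y)))
  expect_lt(max(abs(adj - ref)), 1e-6)
})

test_that("re-adjusting already adjusted data is a near no-op", {
  # location effects re-shrink to essentially zero on a second pass; the
  # residual change is dominated by scale-factor sampling noise, which
  # decays with the per-batch sample size
  d <- make_batch_data(G = 200, n = 800, B = 2, gamma_sd = 0.5, seed = 8)
  m <- fitEbBatchModel(d$X, d$batch, preserve = factor(d$y))
  adj <- applyAdjustment(d$X, m)
  m2 <- fitEbBatchModel(adj, d$batch, preserve = factor(d$y))
  adj2 <- applyAdjustment(adj, m2)
  expect_lt(sqrt(mean((adj2 - adj)^2)), 0.01)
  expect_lt(max(abs(m2@gammaStar)), 0.02)
})

test_that("stepwise adjustment validates inputs and respects step order", {
  coh <- smallCohort(seed = 9, n = 60, genes = 100, reps = 0,
                     nPlates = 4, nSites = 2)
  X <- exprMatrix(coh); md <- sampleInfo(coh)
  expect_identical(adjustStepwise(X, md, steps = character()), X)
  expect_error(adjustStepwise(X, md, steps = "nonexistent"), "absent")
  out <- adjustStepwise(X, md, steps = c("plate", "site"))
  expect_equal(dim(out), dim(X))
  # small-batch error surfaces from the inner fit
  md_bad <- md; md_bad$plate <- factor(seq_len(nrow(md)))
  expect_error(adjustStepwise(X, md_bad, steps = "plate"), ">= 2 samples")
})

test_that("continuous residualisation removes the covariate, keeps diagnosis", {
  set.seed(10)
  n <- 200
  y <- rep_len(c(1, 0), n)
  cv <- rnorm(n)
  g1 <- 2 * cv + 0.5 * y + rnorm(n, 0, 0.1)
  gOrth <- rnorm(n)                       # unrelated to the covariate
  gOrth <- gOrth - cv * sum(gOrth * cv) / sum(cv^2)
  X <- rbind(g1 = g1, g2 = gOrth)
  colnames(X) <- paste0("s", 1:n)
  adj <- residualizeContinuous(X, cv, factor(y))

  # closed-form OLS oracle on the same design
  D <- cbind(1, y, cv)
  bet <- solve(crossprod(D), crossprod(D, g1))
  expect_equal(unname(adj["g1", ]),
               unname(g1 - bet[3] * (cv - mean(cv))), tolerance = 1e-9)
  post <- lm(adj["g1", ] ~ y + cv)
  expect_lt(abs(coef(post)["cv"]), 1e-9)
  expect_equal(unname(coef(post)["y"]), 0.5, tolerance = 0.05)

  # oracle agreement also holds for the near-orthogonal gene
  b2 <- solve(crossprod(D), crossprod(D, gOrth))
  expect_lt(max(abs(adj["g2", ] - (gOrth - b2[3] * (cv - mean(cv))))), 1e-9)

  # a gene with an exactly zero fitted slope is untouched
  gz <- rnorm(n)
  Dq <- qr.Q(qr(D))
  gz <- gz - Dq %*% crossprod(Dq, gz)     # orthogonal to the whole design
  Xz <- rbind(gz = as.numeric(gz)); colnames(Xz) <- paste0("s", 1:n)
  expect_lt(max(abs(residualizeContinuous(Xz, cv, factor(y)) - Xz)), 1e-9)

  expect_error(residualizeContinuous(X, rep(1, n), factor(y)),
               "zero variance")
})
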