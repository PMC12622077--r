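## Build the preserved-design matrix (no intercept; the batch dummies span it)
preserve_design <- function(preserve, n) {
  if (is.null(preserve)) return(matrix(0, n, 0))
  df <- if (is.data.frame(preserve)) preserve
        else data.frame(preserve = preserve)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

eb_iterate <- function(g.hat, d.hat, g.bar, t2, a, b, sdat, conv = 1e-4) {
  n <- ncol(sdat)
  g.old <- g.hat; d.old <- d.hat
  repeat {
    g.new <- (n * t2 * g.hat + d.old * g.bar) / (n * t2 + d.old)
    sum2 <- rowSums((sdat - g.new)^2)
    d.new <- (b + 0.5 * sum2) / (n / 2 + a - 1)
    change <- max(abs(g.new - g.old) / abs(g.old + 1e-12),
                  abs(d.new - d.old) / abs(d.old + 1e-12))
    g.old <- g.new; d.old <- d.new
    if (change < conv) break
  }
  list(gamma = g.new, delta2 = d.new)
}

#' Fit a supervised empirical-Bayes batch model
#'
#' ComBat-style location-scale model for one categorical batch variable.
#' The data are standardised per gene with the preserved design (e.g.
#' diagnosis) retained, per-batch location and scale effects are estimated,
#' and both are shrunk by parametric empirical Bayes with method-of-moments
#' priors (normal prior on locations, inverse-gamma on squared scales).
#' With a single batch the model reduces to the identity (no shrinkage
#' target exists and nothing needs removing).
#'
#' @param matrix features x samples log2 expression matrix.
#' @param batch factor-like batch labels, one per sample; every batch needs
#'   at least two samples.
#' @param preserve design to protect from removal: a vector/factor (e.g.
#'   diagnosis labels) or data.frame of covariates; `NULL` for none.
#' @return a [BatchAdjustModel-class].
#' @export
fitEbBatchModel <- function(matrix, batch, preserve = NULL) {
  batch <- droplevels(as.factor(batch))
  nb <- table(batch)
  if (any(nb < 2))
    stop("every batch needs >= 2 samples; offending: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  n <- ncol(matrix)
  stopifnot(length(batch) == n)
  G <- nrow(matrix)
  batchmod <- vapply(levels(batch), function(l) as.numeric(batch == l),
                     numeric(n))
  mod <- preserve_design(preserve, n)
  if (ncol(mod) > 0) {
    comb <- cbind(batchmod, mod)
    if (qr(comb)$rank < ncol(comb))
      stop("preserved design is confounded with batch")
  }
  design <- cbind(batchmod, mod)
  B <- length(levels(batch))

  B.hat <- solve(crossprod(design), t(design) %*% t(matrix))
  grand <- as.numeric(crossprod(nb / n, B.hat[seq_len(B), , drop = FALSE]))
  var.pooled <- rowMeans((matrix - t(design %*% B.hat))^2)
  var.pooled[var.pooled < 1e-12] <- 1e-12
  beta <- t(B.hat[-seq_len(B), , drop = FALSE])
  if (ncol(mod) > 0) colnames(beta) <- colnames(mod)

  stand.mean <- outer(grand, rep(1, n))
  if (ncol(mod) > 0) stand.mean <- stand.mean + t(mod %*% t(beta))
  sdat <- (matrix - stand.mean) / sqrt(var.pooled)

  gammaStar <- matrix(0, G, B,
                      dimnames = list(rownames(matrix), levels(batch)))
  delta2Star <- matrix(1, G, B,
                       dimnames = list(rownames(matrix), levels(batch)))
  priors <- list(batch = batch, preserve = preserve)
  if (B > 1) {
    for (bl in levels(batch)) {
      idx <- which(batch == bl)
      sb <- sdat[, idx, drop = FALSE]
      g.hat <- rowMeans(sb)
      d.hat <- apply(sb, 1, stats::var)
      g.bar <- mean(g.hat)
      t2 <- stats::var(g.hat)
      m <- mean(d.hat); s2 <- stats::var(d.hat)
      if (!is.finite(s2) || s2 < 1e-12) {
        gammaStar[, bl] <- g.hat
        delta2Star[, bl] <- pmax(d.hat, 1e-12)
        priors[[bl]] <- list(gamma.bar = g.bar, t2 = t2,
                             a.prior = NA, b.prior = NA)
        next
      }
      a <- (2 * s2 + m^2) / s2
      b <- (m * s2 + m^3) / s2
      sol <- eb_iterate(g.hat, d.hat, g.bar, t2, a, b, sb)
      gammaStar[, bl] <- sol$gamma
      delta2Star[, bl] <- pmax(sol$delta2, 1e-12)
      priors[[bl]] <- list(gamma.bar = g.bar, t2 = t2,
                           a.prior = a, b.prior = b)
    }
  }
  new("BatchAdjustModel", features = rownames(matrix),
      batchLevels = levels(batch), alpha = grand, beta = beta,
      sigma2 = var.pooled, gammaStar = gammaStar, delta2Star = delta2Star,
      priors = priors,
      preserveNames = if (ncol(mod)) colnames(mod) else character())
}

#' Apply a fitted batch-adjustment model
#'
#' Standardises the data with the model's per-gene intercept, preserved
#' design and pooled variance, removes the shrunken per-batch location and
#' scale effects, and re-injects the preserved effects:
#' `x_adj = sqrt(sigma2) * (z - gamma*) / sqrt(delta2*) + alpha + X beta`.
#'
#' @param matrix features x samples matrix with the model's feature set.
#' @param model a [BatchAdjustModel-class] fitted on the same samples
#'   (batch assignment and preserved design are carried in the model).
#' @return the adjusted matrix.
#' @export
applyAdjustment <- function(matrix, model) {
  if (!identical(rownames(matrix), model@features))
    stop("feature set differs from the one the model was fitted on")
  batch <- model@priors$batch
  if (ncol(matrix) != length(batch))
    stop("sample count differs from the fitted batch assignment")
  n <- ncol(matrix)
  mod <- preserve_design(model@priors$preserve, n)
  stand.mean <- outer(model@alpha, rep(1, n))
  if (ncol(mod) > 0) stand.mean <- stand.mean + t(mod %*% t(model@beta))
  sdat <- (matrix - stand.mean) / sqrt(model@sigma2)
  for (bl in model@batchLevels) {
    idx <- which(batch == bl)
    sdat[, idx] <- (sdat[, idx, drop = FALSE] - model@gammaStar[, bl]) /
      sqrt(model@delta2Star[, bl])
  }
  sdat * sqrt(model@sigma2) + stand.mean
}

#' Stepwise batch adjustment
#'
#' Applies [fitEbBatchModel()] + [applyAdjustment()] sequentially for each
#' batch variable (default plate then site), preserving the diagnosis
#' effect at every step, and optionally residualises a continuous covariate
#' (e.g. the scaled neutrophil estimate) afterwards.
#'
#' @param matrix features x samples log2 expression matrix.
#' @param metadata per-sample data.frame holding the step variables and the
#'   preserve column, rows aligned with `colnames(matrix)`.
#' @param steps ordered character vector of metadata columns to adjust for.
#' @param preserve metadata column whose effect must be retained (default
#'   `"diagnosis"`); `NULL` for unsupervised adjustment.
#' @param covariate optional numeric vector for a final continuous
#'   residualisation step (see [residualizeContinuous()]).
#' @return the adjusted matrix.
#' @export
adjustStepwise <- function(matrix, metadata, steps = c("plate", "site"),
                           preserve = "diagnosis", covariate = NULL) {
  missing <- setdiff(steps, colnames(metadata))
  if (length(missing))
    stop("step variables absent from metadata: ",
         paste(missing, collapse = ", "))
  pres <- if (is.null(preserve)) NULL else metadata[[preserve]]
  out <- matrix
  for (s in steps) {
    model <- fitEbBatchModel(out, metadata[[s]], preserve = pres)
    out <- applyAdjustment(out, model)
  }
  if (!is.null(covariate))
    out <- residualizeContinuous(out, covariate, pres)
  out
}

#' Residualise a continuous covariate, preserving diagnosis
#'
#' Per gene, fits `x ~ intercept + diagnosis + covariate` by least squares
#' and subtracts only the fitted covariate term (centred, so per-gene means
#' are untouched). This is the continuous-covariate analogue of supervised
#' batch adjustment: the diagnosis effect is estimated jointly and retained.
#'
#' @param matrix features x samples matrix.
#' @param covariate numeric of length `ncol(matrix)`, non-constant.
#' @param diagnosis per-sample labels to preserve; `NULL` to adjust blind.
#' @return the adjusted matrix.
#' @export
residualizeContinuous <- function(matrix, covariate, diagnosis = NULL) {
  if (length(covariate) != ncol(matrix))
    stop("covariate length must equal the number of samples")
  if (stats::sd(covariate) == 0)
    stop("covariate has zero variance")
  D <- cbind(intercept = 1, preserve_design(diagnosis, ncol(matrix)),
             covariate = covariate)
  coefs <- solve(crossprod(D), t(D) %*% t(matrix))
  slope <- coefs[nrow(coefs), ]
  matrix - outer(slope, covariate - mean(covariate))
}
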