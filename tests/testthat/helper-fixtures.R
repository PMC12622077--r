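# Small in-code fixtures shared across test files.

# tiny cohort for fast structural checks
smallCohort <- function(seed = 1, n = 40, genes = 150, reps = 3, ...) {
  generateCohort(cohortConfig(nSubjects = n, nGenes = genes,
                              nDeGenes = genes %/% 10,
                              nReplicateSubjects = reps, seed = seed, ...))
}

# independent penalised-logistic fit by BFGS on the explicit objective:
# summed log-loss + 0.5 * lambda * ||w||^2 (intercept unpenalised)
oracle_ridge_logit <- function(X, y, lambda) {
  p <- ncol(X)
  f <- function(b) {
    eta <- b[1] + X %*% b[-1]
    sum(log1p(exp(eta))) - sum(y * eta) + 0.5 * lambda * sum(b[-1]^2)
  }
  g <- function(b) {
    eta <- as.numeric(b[1] + X %*% b[-1])
    pr <- 1 / (1 + exp(-eta))
    c(sum(pr - y), as.numeric(t(X) %*% (pr - y)) + lambda * b[-1])
  }
  stats::optim(rep(0, p + 1), f, g, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))$par
}

# from-scratch LOOCV of the same classifier: per-fold standardisation,
# oracle fit, held-out linear predictor
oracle_loocv_scores <- function(X, y, lambda = 1) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2, stats::sd); sd[sd < 1e-12] <- 1
    Z <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
    b <- oracle_ridge_logit(Z, y[-i], lambda)
    zi <- (X[i, ] - mu) / sd
    b[1] + sum(zi * b[-1])
  }, numeric(1))
}

# exact hypergeometric upper-tail by direct summation of choose() terms
oracle_hyper_tail <- function(k, N, i, j) {
  xs <- k:min(i, j)
  sum(choose(i, xs) * choose(N - i, j - xs)) / choose(N, j)
}

# from-scratch greedy oracle recomputing relevance and redundancy each step
oracle_mrmr <- function(X, y, L = nrow(X), scheme = "quotient") {
  feats <- rownames(X)
  frel <- function(v) {
    ft <- tryCatch(summary(aov(v ~ factor(y)))[[1]]$`F value`[1],
                   error = function(e) 0)
    if (!is.finite(ft)) 0 else ft
  }
  rel <- vapply(seq_len(nrow(X)), function(i) frel(X[i, ]), numeric(1))
  names(rel) <- feats
  sel <- character()
  for (k in seq_len(L)) {
    cand <- setdiff(feats, sel)
    score <- vapply(cand, function(f) {
      if (!length(sel)) return(rel[f])
      red <- mean(vapply(sel, function(s) {
        r <- suppressWarnings(cor(X[f, ], X[s, ]))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1)))
      red <- max(red, 1e-6)
      if (scheme == "quotient") rel[f] / red else rel[f] - red
    }, numeric(1))
    sel <- c(sel, cand[order(-score, cand)][1])
  }
  sel
}
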