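#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Newton/IRLS for L2-penalised logistic regression.
// X carries an explicit intercept column (index 0) which is never penalised;
// the penalty is 0.5 * lambda * ||w||^2 added to the summed log-loss, i.e. the
// common library default with unit regularisation strength when lambda = 1.
static vec fit_ridge_logit(const mat& X, const vec& y, double lambda,
                           vec beta, int maxit, double tol) {
  const uword p = X.n_cols;
  vec pen(p); pen.fill(lambda); pen(0) = 0.0;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    vec pr = 1.0 / (1.0 + exp(-eta));
    vec w = pr % (1.0 - pr);
    w.transform([](double v){ return v < 1e-9 ? 1e-9 : v; });
    vec g = X.t() * (y - pr) - pen % beta;
    mat H = X.t() * (X.each_col() % w);
    H.diag() += pen;
    vec step = solve(H, g, solve_opts::likely_sympd);
    beta += step;
    if (norm(step, "inf") < tol) break;
  }
  return beta;
}

static void col_stats(const mat& X, rowvec& mu, rowvec& sd) {
  mu = mean(X, 0);
  sd = stddev(X, 0, 0);  // divisor n-1
  sd.transform([](double v){ return v < 1e-12 ? 1.0 : v; });
}

// [[Rcpp::export]]
Rcpp::List cpp_ridge_logistic(const arma::mat& X, const arma::vec& y,
                              double lambda, bool standardize) {
  const uword n = X.n_rows, p = X.n_cols;
  rowvec mu(p, fill::zeros), sd(p, fill::ones);
  mat Xs = X;
  if (standardize) {
    col_stats(X, mu, sd);
    Xs.each_row() -= mu;
    Xs.each_row() /= sd;
  }
  mat D(n, p + 1);
  D.col(0).ones();
  D.cols(1, p) = Xs;
  vec beta(p + 1, fill::zeros);
  beta = fit_ridge_logit(D, y, lambda, beta, 50, 1e-10);
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("center") = mu.t(),
    Rcpp::Named("scale") = sd.t());
}

// Leave-one-out cross-validation: for each sample, standardise on the n-1
// training rows, fit, and record the held-out linear predictor. Warm-started
// from the full-data fit so each fold needs only a few Newton steps.
// [[Rcpp::export]]
arma::vec cpp_loocv_ridge_logistic(const arma::mat& X, const arma::vec& y,
                                   double lambda, bool standardize) {
  const uword n = X.n_rows, p = X.n_cols;
  vec scores(n);

  rowvec mu0(p, fill::zeros), sd0(p, fill::ones);
  mat Xs = X;
  if (standardize) {
    col_stats(X, mu0, sd0);
    Xs.each_row() -= mu0;
    Xs.each_row() /= sd0;
  }
  mat D(n, p + 1);
  D.col(0).ones();
  D.cols(1, p) = Xs;
  vec beta_full = fit_ridge_logit(D, y, lambda, vec(p + 1, fill::zeros),
                                  50, 1e-10);

  mat Xtr(n - 1, p);
  vec ytr(n - 1);
  for (uword i = 0; i < n; ++i) {
    uword k = 0;
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      Xtr.row(k) = X.row(j);
      ytr(k) = y(j);
      ++k;
    }
    rowvec mu(p, fill::zeros), sd(p, fill::ones);
    mat Xtrs = Xtr;
    if (standardize) {
      col_stats(Xtr, mu, sd);
      Xtrs.each_row() -= mu;
      Xtrs.each_row() /= sd;
    }
    mat Dtr(n - 1, p + 1);
    Dtr.col(0).ones();
    Dtr.cols(1, p) = Xtrs;
    vec beta = fit_ridge_logit(Dtr, ytr, lambda, beta_full, 25, 1e-8);
    rowvec xi = (X.row(i) - mu) / sd;
    scores(i) = beta(0) + dot(xi, beta.subvec(1, p));
  }
  return scores;
}
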