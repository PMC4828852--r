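// Bidirectional AIC stepwise search for logistic regression.
//
// The model-combination step scans hundreds of candidate additions and
// deletions per round, each requiring a small logistic fit; doing the IRLS
// loops in Armadillo keeps the whole search fast enough for the
// resampling studies built on top of it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// IRLS for logistic regression on a design matrix that already carries the
// intercept column.  Mirrors stats::glm.fit: deviance-change convergence at
// 1e-8, at most 25 iterations.  Returns the deviance; coefficients via
// reference.
static double logistic_irls(const mat& X, const vec& y, vec& beta,
                            bool warm_start) {
  const uword n = X.n_rows, p = X.n_cols;
  if (!warm_start || beta.n_elem != p) beta = zeros<vec>(p);
  double dev = datum::inf;
  for (int it = 0; it < 25; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, 1e-10, 1.0 - 1e-10);
    vec w = mu % (1.0 - mu);
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    A.diag() += 1e-12;  // guard against underflowing weights
    vec b = Xw.t() * z;
    vec beta_new;
    if (!solve(beta_new, A, b, solve_opts::no_approx)) {
      beta_new = pinv(A) * b;
    }
    beta = beta_new;
    eta = X * beta;
    mu = clamp(1.0 / (1.0 + exp(-eta)), 1e-10, 1.0 - 1e-10);
    double dev_new = -2.0 * sum(y % log(mu) + (1.0 - y) % log(1.0 - mu));
    if (std::abs(dev_new - dev) / (std::abs(dev_new) + 0.1) < 1e-8) {
      return dev_new;
    }
    dev = dev_new;
  }
  return dev;
}

static mat design_for(const mat& X, const std::vector<uword>& sel) {
  mat D(X.n_rows, sel.size() + 1);
  D.col(0).ones();
  for (size_t i = 0; i < sel.size(); ++i) D.col(i + 1) = X.col(sel[i]);
  return D;
}

// [[Rcpp::export(name = ".aic_stepwise_cpp")]]
Rcpp::IntegerVector aic_stepwise_cpp(const arma::mat& X,
                                     const arma::vec& y,
                                     int max_steps = 1000) {
  const uword k = X.n_cols;
  std::vector<uword> sel;
  vec cur_beta;
  double cur_dev = logistic_irls(design_for(X, sel), y, cur_beta, false);
  double cur_aic = cur_dev + 2.0;

  for (int step = 0; step < max_steps; ++step) {
    double best_aic = cur_aic;
    std::vector<uword> best_sel;
    bool found = false;

    std::vector<bool> in_sel(k, false);
    for (uword j : sel) in_sel[j] = true;

    // additions, warm-started from the current fit
    for (uword j = 0; j < k; ++j) {
      if (in_sel[j]) continue;
      std::vector<uword> cand = sel;
      cand.push_back(j);
      vec beta = join_vert(cur_beta, zeros<vec>(1));
      double dev = logistic_irls(design_for(X, cand), y, beta, true);
      double aic = dev + 2.0 * (cand.size() + 1.0);
      if (aic < best_aic - 1e-8) { best_aic = aic; best_sel = cand; found = true; }
    }
    // deletions
    for (size_t d = 0; d < sel.size(); ++d) {
      std::vector<uword> cand = sel;
      cand.erase(cand.begin() + d);
      vec beta = cur_beta;
      beta.shed_row(d + 1);
      double dev = logistic_irls(design_for(X, cand), y, beta, true);
      double aic = dev + 2.0 * (cand.size() + 1.0);
      if (aic < best_aic - 1e-8) { best_aic = aic; best_sel = cand; found = true; }
    }

    if (!found) break;
    sel = best_sel;
    cur_dev = logistic_irls(design_for(X, sel), y, cur_beta, false);
    cur_aic = cur_dev + 2.0 * (sel.size() + 1.0);
  }

  Rcpp::IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i] + 1;  // 1-based
  return out;
}
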