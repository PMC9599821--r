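// Newton-Raphson logistic regression with step halving.
// Hot path of the bootstrap: each replicate refits the imputation,
// mediator and outcome models, so the fit must cost milliseconds.
// Matches the stats::glm IRLS solution (checked in the test suite).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double binom_deviance(const vec& y, const vec& eta) {
  double d = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    const double e = eta[i];
    // stable log(1 + exp(e))
    const double l1p = e > 0 ? e + std::log1p(std::exp(-e))
                             : std::log1p(std::exp(e));
    d += y[i] * e - l1p;
  }
  return -2.0 * d;
}

// [[Rcpp::export(name = ".logit_newton")]]
Rcpp::List logit_newton(const arma::mat& X, const arma::vec& y,
                        const arma::vec& start, int max_iter, double tol) {
  vec beta = start;
  vec eta = X * beta;
  double d_old = binom_deviance(y, eta);
  bool converged = false, singular = false;

  for (int it = 0; it < max_iter && !converged; ++it) {
    const vec p = 1.0 / (1.0 + exp(-eta));
    const vec w = p % (1.0 - p);
    const mat H = X.t() * (X.each_col() % w);
    const vec g = X.t() * (y - p);
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx) || !step.is_finite()) {
      singular = true;
      break;
    }
    double h = 1.0, d_new = 0.0;
    vec cand, eta_c;
    for (;;) {
      cand = beta + h * step;
      eta_c = X * cand;
      d_new = binom_deviance(y, eta_c);
      if (d_new <= d_old + 1e-8 || h < 1e-4) break;
      h *= 0.5;
    }
    const double moved = max(abs(h * step));
    beta = cand;
    eta = eta_c;
    d_old = d_new;
    if (moved < tol) converged = true;
  }
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("deviance") = d_old,
      Rcpp::Named("singular") = singular);
}
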