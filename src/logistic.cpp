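// Fast per-variant logistic regression (IRLS) for trait association scans.
// Fits trait ~ covariates + dosage for every column of G and returns the
// Wald statistic ingredients for the dosage term, flagging non-convergence
// and (quasi-)separation instead of dropping variants silently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List logistic_scan_cpp(const arma::mat& C, const arma::mat& G,
                             const arma::vec& y, int maxit = 30,
                             double tol = 1e-8) {
  const uword n = C.n_rows, m = G.n_cols, pc = C.n_cols;
  vec beta_out(m, fill::value(datum::nan));
  vec se_out(m, fill::value(datum::nan));
  ivec conv(m, fill::zeros);
  ivec sep(m, fill::zeros);

  for (uword j = 0; j < m; ++j) {
    vec g = G.col(j);
    uvec ok = find_finite(g);
    if (ok.n_elem < pc + 3) continue;
    mat X(ok.n_elem, pc + 1);
    X.cols(0, pc - 1) = C.rows(ok);
    X.col(pc) = g.elem(ok);
    vec yy = y.elem(ok);
    // monomorphic dosage among called individuals: undefined
    if (X.col(pc).max() - X.col(pc).min() < 1e-12) continue;

    vec b(pc + 1, fill::zeros);
    b(0) = std::log((mean(yy) + 1e-6) / (1 - mean(yy) + 1e-6));
    bool converged = false, separated = false;
    mat XtWX;
    for (int it = 0; it < maxit; ++it) {
      vec eta = X * b;
      eta = clamp(eta, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w = clamp(w, 1e-10, 0.25);
      XtWX = X.t() * (X.each_col() % w);
      vec grad = X.t() * (yy - mu);
      vec step;
      bool okstep = solve(step, XtWX, grad, solve_opts::no_approx);
      if (!okstep) { separated = true; break; }
      b += step;
      if (norm(step, "inf") < tol) { converged = true; break; }
    }
    vec eta = clamp(X * b, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    // refresh the information matrix at the final coefficients so the Wald
    // s.e. matches the converged fit, not the penultimate IRLS step
    vec w_fin = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    XtWX = X.t() * (X.each_col() % w_fin);
    // fitted probabilities driven to 0/1 matching y, or an exploding slope,
    // signal (quasi-)separation: the Wald test is unusable there
    if (std::abs(b(pc)) > 15.0) separated = true;
    uvec cases = find(yy > 0.5), ctrls = find(yy < 0.5);
    if (cases.n_elem > 0 && ctrls.n_elem > 0 &&
        mu.elem(cases).min() > 1.0 - 1e-6 && mu.elem(ctrls).max() < 1e-6)
      separated = true;

    mat cov;
    bool okcov = inv_sympd(cov, XtWX);
    if (!okcov) {
      sep(j) = 1;
      continue;
    }
    beta_out(j) = b(pc);
    se_out(j) = std::sqrt(cov(pc, pc));
    conv(j) = converged ? 1 : 0;
    sep(j) = separated ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta_out,
                            Rcpp::Named("se") = se_out,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("separated") = sep);
}
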