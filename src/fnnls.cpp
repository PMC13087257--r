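// Fast non-negative least squares on the normal equations (Bro & De Jong 1997),
// used as the inner solver of the regularised inversion.  Works on AtA / Atb so
// the Tikhonov penalty and the normalisation row can be folded in by the caller.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List fnnls_cpp(const arma::mat& AtA, const arma::vec& Atb,
                     double tol = -1.0, int maxiter = -1) {
  const uword n = AtA.n_cols;
  if (maxiter < 0) maxiter = 30 * (int)n;
  if (tol < 0) tol = 10.0 * datum::eps * norm(AtA, 1) * n;

  uvec P(n, fill::zeros);          // passive (free) set indicator
  vec x(n, fill::zeros);
  vec w = Atb - AtA * x;           // negative gradient

  int iter = 0;
  while (true) {
    uvec R = find(P == 0);
    if (R.n_elem == 0) break;
    vec wR = w.elem(R);
    if (wR.max() <= tol) break;
    uword t = R(wR.index_max());
    P(t) = 1;

    // inner loop: solve on passive set, backtrack if negatives appear
    while (true) {
      if (++iter > maxiter) {
        return Rcpp::List::create(Rcpp::Named("x") = x,
                                  Rcpp::Named("passive") = find(P == 1) + 1,
                                  Rcpp::Named("converged") = false);
      }
      uvec Pidx = find(P == 1);
      if (Pidx.n_elem == 0) break;
      vec s(n, fill::zeros);
      vec sP;
      bool ok = solve(sP, AtA.submat(Pidx, Pidx), Atb.elem(Pidx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) sP = pinv(AtA.submat(Pidx, Pidx)) * Atb.elem(Pidx);
      s.elem(Pidx) = sP;
      if (sP.min() > 0) { x = s; break; }
      // step toward s until first passive variable hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < Pidx.n_elem; ++k) {
        uword j = Pidx(k);
        if (s(j) <= 0) {
          double a = x(j) / (x(j) - s(j));
          if (a < alpha) alpha = a;
        }
      }
      x += alpha * (s - x);
      for (uword j = 0; j < n; ++j) {
        if (P(j) == 1 && x(j) <= tol) { x(j) = 0.0; P(j) = 0; }
      }
    }
    w = Atb - AtA * x;
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("passive") = find(P == 1) + 1,
                            Rcpp::Named("converged") = true);
}
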