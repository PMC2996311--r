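// Variable-projection least squares for sums of exponentials fitted to
// unit-width histograms. Bins are consecutive integers, so sums over the full
// bin range and over runs of zero-count bins are geometric series; the
// objective is exact and costs O(#nonzero * k) per evaluation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// sum_{t=0..L-1} exp(-c (x0 + t)), c > 0
static inline double geom_sum(double c, double x0, double L) {
  return std::exp(-c * x0) * (-std::expm1(-c * L)) / (-std::expm1(-c));
}

// Returns c(ss, a_1..a_k), or a single NA on failure (singular system /
// non-finite result). taus must be positive and finite (checked in R).
// [[Rcpp::export]]
NumericVector varpro_solve_cpp(NumericVector taus, NumericVector x_nz,
                               NumericVector y_nz, NumericVector run_start,
                               NumericVector run_len, double x0, double m) {
  const int k = taus.size();
  const int nnz = x_nz.size();
  const int nruns = run_start.size();
  NumericVector fail(1, NA_REAL);

  arma::vec r(k);
  for (int i = 0; i < k; ++i) r[i] = 1.0 / taus[i];

  // Gram matrix over all bins (geometric series over the full range)
  arma::mat G(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j)
      G(i, j) = G(j, i) = geom_sum(r[i] + r[j], x0, m);

  // rhs over nonzero bins
  arma::mat E(nnz, k);
  arma::vec y(nnz);
  for (int t = 0; t < nnz; ++t) {
    y[t] = y_nz[t];
    for (int i = 0; i < k; ++i) E(t, i) = std::exp(-x_nz[t] * r[i]);
  }
  arma::vec b = E.t() * y;

  arma::vec a;
  bool ok = arma::solve(a, G, b, arma::solve_opts::no_approx);
  if (!ok || !a.is_finite()) return fail;

  arma::vec resid = y - E * a;
  double ss = arma::dot(resid, resid);

  // zero-run contribution: f(x)^2 summed in closed form
  for (int q = 0; q < nruns; ++q)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        ss += a[i] * a[j] * geom_sum(r[i] + r[j], run_start[q], run_len[q]);

  if (!std::isfinite(ss)) return fail;
  NumericVector out(k + 1);
  out[0] = ss;
  for (int i = 0; i < k; ++i) out[i + 1] = a[i];
  return out;
}
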