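// EM iteration core for the mixture of linear trajectory models.
//
// Because every component is a straight line with Gaussian residuals, a
// patient's contribution to both EM steps reduces to six sufficient
// statistics of their (t, y) rows: n_i, sum t, sum t^2, sum y, sum t*y,
// sum y^2.  Each iteration is therefore O(n_patients * K), independent of
// the number of observations.  The observed-data log-likelihood trace is
// returned for the monotonicity contract.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// stats: n x 6 matrix with columns (n_i, St, Stt, Sy, Sty, Syy)
// [[Rcpp::export]]
List em_core(NumericMatrix stats, int K, IntegerVector init, double tol,
             int max_iter, double sigma_floor, double weight_floor) {
  const int n = stats.nrow();
  NumericMatrix z(n, K);
  for (int i = 0; i < n; i++) z(i, init[i]) = 1.0;
  NumericVector a(K), b(K), sig(K), w(K);
  std::vector<double> trace;
  bool degenerate = false, converged = false;
  int underflow = 0;
  double loglik = R_NegInf;
  const double c0 = -0.5 * std::log(2.0 * M_PI);
  const double s2min = sigma_floor * sigma_floor;
  std::vector<double> logw(K), Lrow(K);

  int iter = 0;
  while (iter < max_iter) {
    iter++;
    // M-step: per-component WLS from responsibility-weighted patient stats
    for (int k = 0; k < K && !degenerate; k++) {
      double Sw = 0, Swt = 0, Swtt = 0, Swy = 0, Swty = 0, Swyy = 0, Sz = 0;
      for (int i = 0; i < n; i++) {
        const double zi = z(i, k);
        Sz += zi;
        Sw += zi * stats(i, 0); Swt += zi * stats(i, 1);
        Swtt += zi * stats(i, 2); Swy += zi * stats(i, 3);
        Swty += zi * stats(i, 4); Swyy += zi * stats(i, 5);
      }
      const double det = Sw * Swtt - Swt * Swt;
      if (Sz < weight_floor || det <= 0) { degenerate = true; break; }
      b[k] = (Sw * Swty - Swt * Swy) / det;
      a[k] = (Swy - b[k] * Swt) / Sw;
      const double rss = Swyy - 2 * a[k] * Swy - 2 * b[k] * Swty +
        a[k] * a[k] * Sw + 2 * a[k] * b[k] * Swt + b[k] * b[k] * Swtt;
      double s2 = rss / Sw;
      if (s2 < s2min) s2 = s2min;
      sig[k] = std::sqrt(s2);
      w[k] = Sz / n;
      if (!R_finite(a[k]) || !R_finite(b[k]) || !R_finite(sig[k])) {
        degenerate = true;
      }
    }
    if (degenerate) break;

    // E-step in log space
    for (int k = 0; k < K; k++) logw[k] = std::log(w[k]);
    double ll = 0;
    for (int i = 0; i < n; i++) {
      double mx = R_NegInf;
      for (int k = 0; k < K; k++) {
        const double q = stats(i, 5) - 2 * a[k] * stats(i, 3) -
          2 * b[k] * stats(i, 4) + a[k] * a[k] * stats(i, 0) +
          2 * a[k] * b[k] * stats(i, 1) + b[k] * b[k] * stats(i, 2);
        Lrow[k] = stats(i, 0) * (c0 - std::log(sig[k])) -
          0.5 * q / (sig[k] * sig[k]) + logw[k];
        if (Lrow[k] > mx) mx = Lrow[k];
      }
      if (!R_finite(mx)) {  // all densities underflowed: uniform posterior
        underflow++;
        for (int k = 0; k < K; k++) z(i, k) = 1.0 / K;
        continue;
      }
      double s = 0;
      for (int k = 0; k < K; k++) {
        z(i, k) = std::exp(Lrow[k] - mx);
        s += z(i, k);
      }
      for (int k = 0; k < K; k++) z(i, k) /= s;
      ll += mx + std::log(s);
    }
    trace.push_back(ll);
    const double rel = std::fabs(ll - loglik) /
      (std::fabs(loglik) + DBL_EPSILON);
    const bool had_prev = R_finite(loglik);
    loglik = ll;
    if (had_prev && rel < tol) { converged = true; break; }
  }

  return List::create(
    _["intercept"] = a, _["slope"] = b, _["residual_sd"] = sig,
    _["weight"] = w, _["z"] = z, _["loglik"] = loglik,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_iter"] = (int) trace.size(), _["converged"] = converged,
    _["degenerate"] = degenerate, _["n_underflow"] = underflow);
}
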