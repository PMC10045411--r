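// Artificial-centering hit-and-run sampling of the flux polytope
// {v : S v = 0, lb <= v <= ub}. Directions are drawn through stored
// warmup points (FVA extreme points), so every iterate stays in the
// affine hull of feasible points and S v = 0 is preserved to solver
// precision without reprojection. Uses R's RNG, so set.seed() makes
// runs bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".achr_sample")]]
NumericMatrix achr_sample(const NumericMatrix &warmup,
                          const NumericVector &lb,
                          const NumericVector &ub,
                          int n_samples, int thinning) {
  const int k = warmup.nrow(), n = warmup.ncol();
  const double dir_tol = 1e-10;

  std::vector<double> center(n, 0.0), x(n), d(n);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < n; ++j) center[j] += warmup(i, j) / k;
  x.assign(center.begin(), center.end());

  NumericMatrix out(n_samples, n);
  long total = (long)n_samples * thinning;
  long cnt = 1;  // points contributing to the running center
  int stored = 0;

  for (long step = 0; step < total; ++step) {
    int i = (int)std::floor(unif_rand() * k);
    if (i >= k) i = k - 1;
    double nrm = 0.0;
    for (int j = 0; j < n; ++j) {
      d[j] = warmup(i, j) - center[j];
      nrm += d[j] * d[j];
    }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-12) { unif_rand(); continue; }
    for (int j = 0; j < n; ++j) d[j] /= nrm;

    double tmin = -1e30, tmax = 1e30;
    for (int j = 0; j < n; ++j) {
      if (std::fabs(d[j]) < dir_tol) continue;
      double lo = (lb[j] - x[j]) / d[j];
      double hi = (ub[j] - x[j]) / d[j];
      if (d[j] > 0) {
        if (lo > tmin) tmin = lo;
        if (hi < tmax) tmax = hi;
      } else {
        if (hi > tmin) tmin = hi;
        if (lo < tmax) tmax = lo;
      }
    }
    double t;
    if (tmax <= tmin) t = 0.0;
    else t = tmin + unif_rand() * (tmax - tmin);

    for (int j = 0; j < n; ++j) {
      x[j] += t * d[j];
      if (x[j] < lb[j]) x[j] = lb[j];
      if (x[j] > ub[j]) x[j] = ub[j];
      center[j] = (center[j] * cnt + x[j]) / (cnt + 1);
    }
    ++cnt;

    if ((step + 1) % thinning == 0 && stored < n_samples) {
      for (int j = 0; j < n; ++j) out(stored, j) = x[j];
      ++stored;
    }
  }
  return out;
}
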