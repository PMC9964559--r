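// Artificial-centering hit-and-run (ACHR) over a polytope expressed in
// null-space coordinates: points u with Ain * u <= bin, mapped back to
// flux space as v = v0 + N * u by the R caller.
//
// Directions are (stored iterate - running center), the "artificial
// centering" trick that adapts step directions to the polytope's shape.
// R's RNG is used throughout so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// Atin is the TRANSPOSED inequality matrix (k x m): column j holds the
// normal of constraint j, so the per-constraint dot products below walk
// contiguous memory.
// [[Rcpp::export]]
NumericMatrix achr_chain(NumericMatrix Atin, NumericVector bin, int k,
                         int n_keep, int warmup, int thin) {
  const int m = Atin.ncol();
  const double tol = 1e-12;
  const int total = warmup + n_keep * thin;

  std::vector<double> u(k, 0.0), d(k), center(k, 0.0);
  // store all iterates for direction selection
  std::vector< std::vector<double> > store;
  store.reserve(total + 1);
  store.push_back(u);

  // cache Ain * u incrementally
  std::vector<double> au(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *col = &Atin(0, j);
    for (int i = 0; i < k; ++i) s += col[i] * u[i];
    au[j] = s;
  }

  NumericMatrix kept(k, n_keep);
  int kept_n = 0, since = 0;
  long n_seen = 1;

  for (int step = 0; step < total; ++step) {
    // direction: random gaussian during early steps, ACHR afterwards
    bool achr = (int)store.size() > std::max(10, k + 2);
    if (achr) {
      int pick = (int)std::floor(unif_rand() * store.size());
      if (pick >= (int)store.size()) pick = store.size() - 1;
      double nrm = 0.0;
      for (int i = 0; i < k; ++i) {
        d[i] = store[pick][i] - center[i];
        nrm += d[i] * d[i];
      }
      nrm = std::sqrt(nrm);
      if (nrm < tol) achr = false; else
        for (int i = 0; i < k; ++i) d[i] /= nrm;
    }
    if (!achr) {
      double nrm = 0.0;
      for (int i = 0; i < k; ++i) { d[i] = norm_rand(); nrm += d[i] * d[i]; }
      nrm = std::sqrt(nrm);
      for (int i = 0; i < k; ++i) d[i] /= nrm;
    }

    // chord limits along d
    double tmin = -std::numeric_limits<double>::infinity();
    double tmax = std::numeric_limits<double>::infinity();
    std::vector<double> ad(m);
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      const double *col = &Atin(0, j);
      for (int i = 0; i < k; ++i) s += col[i] * d[i];
      ad[j] = s;
      double slack = bin[j] - au[j];
      if (s > tol) { double t = slack / s; if (t < tmax) tmax = t; }
      else if (s < -tol) { double t = slack / s; if (t > tmin) tmin = t; }
      else if (slack < -1e-8) { tmin = 1.0; tmax = 0.0; }  // infeasible row
    }
    double t = 0.0;
    if (tmax > tmin && R_finite(tmax) && R_finite(tmin)) {
      t = tmin + unif_rand() * (tmax - tmin);
    }
    if (t != 0.0) {
      for (int i = 0; i < k; ++i) u[i] += t * d[i];
      for (int j = 0; j < m; ++j) au[j] += t * ad[j];
    }

    // running center over all iterates
    n_seen++;
    for (int i = 0; i < k; ++i)
      center[i] += (u[i] - center[i]) / (double)n_seen;
    store.push_back(u);

    if (step >= warmup) {
      if (++since == thin) {
        since = 0;
        if (kept_n < n_keep) {
          for (int i = 0; i < k; ++i) kept(i, kept_n) = u[i];
          kept_n++;
        }
      }
    }
  }
  return kept;
}
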