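#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gaussian product-kernel density estimate evaluated at query points.
// points: n x d data matrix, query: N x d, bw: per-dimension bandwidths.
// f(q) = (1 / (n (2 pi)^{d/2} prod b_j)) sum_i exp(-0.5 sum_j ((q_j - x_ij)/b_j)^2)
// Kernel terms with squared standardized distance > 120 contribute
// < 1e-26 of a central term and are dropped. Because z^2 >= z_1^2, the
// cutoff lets us sort the data on the first axis and scan only the
// window |q_1 - x_1| <= sqrt(120) b_1 for each query.
// [[Rcpp::export(name = ".kde_eval_cpp")]]
NumericVector kde_eval_cpp(NumericMatrix points, NumericMatrix query,
                           NumericVector bw) {
  const int n = points.nrow(), d = points.ncol(), N = query.nrow();
  const double CUT = 120.0;
  if (query.ncol() != d || bw.size() != d)
    stop("dimension mismatch between points, query and bandwidths");
  std::vector<double> inv_b(d);
  double log_norm = -0.5 * d * std::log(2.0 * M_PI) - std::log((double)n);
  for (int j = 0; j < d; ++j) {
    if (bw[j] <= 0) stop("bandwidths must be positive");
    inv_b[j] = 1.0 / bw[j];
    log_norm -= std::log(bw[j]);
  }
  const double norm = std::exp(log_norm);

  // data sorted by first coordinate, stored column-contiguous
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return points(a, 0) < points(b, 0);
  });
  std::vector<double> pd((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i) pd[(size_t)j * n + i] = points(ord[i], j);
  const double *x1 = &pd[0];
  const double halfwin = std::sqrt(CUT) * bw[0];

  NumericVector out(N);
  std::vector<double> qv(d);
  for (int q = 0; q < N; ++q) {
    for (int j = 0; j < d; ++j) qv[j] = query(q, j);
    const double *lo = std::lower_bound(x1, x1 + n, qv[0] - halfwin);
    const double *hi = std::upper_bound(lo, x1 + n, qv[0] + halfwin);
    double acc = 0.0;
    for (const double *p = lo; p < hi; ++p) {
      const int i = (int)(p - x1);
      double z = (qv[0] - x1[i]) * inv_b[0];
      double z2 = z * z;
      for (int j = 1; j < d && z2 <= CUT; ++j) {
        z = (qv[j] - pd[(size_t)j * n + i]) * inv_b[j];
        z2 += z * z;
      }
      if (z2 <= CUT) acc += std::exp(-0.5 * z2);
    }
    out[q] = acc * norm;
  }
  return out;
}
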