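#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-kernel density estimates for many genes at once, each gene on its
// own uniform grid.  vals is genes x samples (NA = missing, skipped); from and
// dx give each gene's grid origin and spacing; bw is the per-gene bandwidth.
// Each row of the result is renormalized so its trapezoidal integral is 1.
// Rows with fewer than min_n usable values are returned as NA.
// [[Rcpp::export(name = ".kde_batch_cpp")]]
NumericMatrix kde_batch_cpp(NumericMatrix vals, NumericVector from,
                            NumericVector dx, int ng, NumericVector bw,
                            int min_n) {
  const int G = vals.nrow(), n = vals.ncol();
  const double inv_sqrt2pi = 0.3989422804014327;
  NumericMatrix out(G, ng);
  for (int g = 0; g < G; ++g) {
    if (!R_finite(bw[g]) || bw[g] <= 0.0) {
      for (int k = 0; k < ng; ++k) out(g, k) = NA_REAL;
      continue;
    }
    std::vector<double> dens(ng, 0.0);
    int used = 0;
    const double f = from[g], d = dx[g], h = bw[g];
    for (int j = 0; j < n; ++j) {
      const double v = vals(g, j);
      if (!R_finite(v)) continue;
      ++used;
      for (int k = 0; k < ng; ++k) {
        const double z = (f + d * k - v) / h;
        dens[k] += std::exp(-0.5 * z * z);
      }
    }
    if (used < min_n) {
      for (int k = 0; k < ng; ++k) out(g, k) = NA_REAL;
      continue;
    }
    const double scale = inv_sqrt2pi / (used * h);
    double integral = 0.0;
    for (int k = 0; k < ng; ++k) {
      dens[k] *= scale;
      integral += dens[k];
    }
    integral -= 0.5 * (dens[0] + dens[ng - 1]);
    integral *= d;
    for (int k = 0; k < ng; ++k) out(g, k) = dens[k] / integral;
  }
  return out;
}
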