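#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing; sigma per axis in voxel units (0 skips the
// axis). Borders handled by kernel renormalization (no flux from outside).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nax[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    for (int t = -r; t <= r; ++t)
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
    const int nl = nax[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    const R_xlen_t nlines = n / nl;
    for (R_xlen_t l = 0; l < nlines; ++l) {
      // decompose line index into the two other axes
      R_xlen_t base;
      if (ax == 0) {
        base = l * (R_xlen_t)nx;
      } else if (ax == 1) {
        R_xlen_t i = l % nx, k = l / nx;
        base = i + (R_xlen_t)nx * ny * k;
      } else {
        base = l;
      }
      for (int p = 0; p < nl; ++p) {
        double acc = 0, wsum = 0;
        int t0 = std::max(-r, -p), t1 = std::min(r, nl - 1 - p);
        for (int t = t0; t <= t1; ++t) {
          double w = ker[t + r];
          acc += w * a[base + (R_xlen_t)(p + t) * st];
          wsum += w;
        }
        b[base + (R_xlen_t)p * st] = acc / wsum;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
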