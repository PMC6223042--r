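#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double beta3(double s) {
  double a = std::fabs(s);
  if (a < 1.0) return 2.0 / 3.0 - a * a + a * a * a / 2.0;
  if (a < 2.0) { double t = 2.0 - a; return t * t * t / 6.0; }
  return 0.0;
}

static inline double beta3d(double s) {
  double a = std::fabs(s);
  if (a < 1.0) return -2.0 * s + 1.5 * s * a;
  if (a < 2.0) { double t = 2.0 - a; return (s > 0 ? -1.0 : 1.0) * t * t / 2.0; }
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Joint histogram counts over nbins x nbins cells. fbin: 0-based hard bin
// index of the fixed value per sample. mcoord: continuous bin coordinate of
// the moving value (bin centre kappa sits at coordinate kappa). With
// parzen = TRUE the moving axis is spread with a cubic B-spline kernel
// (weights clamped into range, so total mass = N); otherwise hard-binned by
// rounding the coordinate.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(IntegerVector fbin, NumericVector mcoord,
                             int nbins, bool parzen) {
  const R_xlen_t n = fbin.size();
  NumericMatrix h(nbins, nbins);
  for (R_xlen_t i = 0; i < n; ++i) {
    int fi = clampi(fbin[i], 0, nbins - 1);
    double c = mcoord[i];
    if (!parzen) {
      int k = clampi((int)std::lround(c), 0, nbins - 1);
      h(fi, k) += 1.0;
    } else {
      int k0 = (int)std::floor(c) - 1;
      for (int a = 0; a < 4; ++a) {
        int k = k0 + a;
        double w = beta3(c - k);
        if (w == 0) continue;
        h(fi, clampi(k, 0, nbins - 1)) += w;
      }
    }
  }
  return h;
}

// Per-sample entropy derivative terms for MI/NMI gradients:
//   A_i = sum_k beta3'(c_i - k) * log p(f_i, k)
//   B_i = sum_k beta3'(c_i - k) * log pM(k)
// logp: nbins x nbins matrix of log joint probabilities (any value at empty
// cells; such cells receive ~zero kernel weight in the interior), logpm:
// log marginal of the moving axis.
// [[Rcpp::export]]
NumericMatrix cpp_entropy_grad_terms(IntegerVector fbin, NumericVector mcoord,
                                     NumericMatrix logp, NumericVector logpm) {
  const int nbins = logpm.size();
  const R_xlen_t n = fbin.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    int fi = clampi(fbin[i], 0, nbins - 1);
    double c = mcoord[i];
    int k0 = (int)std::floor(c) - 1;
    double A = 0, B = 0;
    for (int a = 0; a < 4; ++a) {
      int k = k0 + a;
      double w = beta3d(c - k);
      if (w == 0) continue;
      int kc = clampi(k, 0, nbins - 1);
      A += w * logp(fi, kc);
      B += w * logpm[kc];
    }
    out(i, 0) = A;
    out(i, 1) = B;
  }
  return out;
}
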