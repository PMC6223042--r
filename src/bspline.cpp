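#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline kernel beta3 and its derivative, support (-2, 2).
static inline double beta3(double s) {
  double a = std::fabs(s);
  if (a < 1.0) return 2.0 / 3.0 - a * a + a * a * a / 2.0;
  if (a < 2.0) { double t = 2.0 - a; return t * t * t / 6.0; }
  return 0.0;
}

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Free-form deformation displacement. coef: ncp x 3 matrix of control-point
// displacements (mm), control grid of dim gdim (gx, gy, gz) in grid units.
// pts: N x 3 continuous grid coordinates (point p sits at grid coord
// (p - grid_origin) / grid_spacing). Points whose 4x4x4 support is not fully
// inside the control grid get zero displacement.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericMatrix coef, IntegerVector gdim,
                               NumericMatrix pts) {
  const int gx = gdim[0], gy = gdim[1], gz = gdim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix - 1 < 0 || iy - 1 < 0 || iz - 1 < 0 ||
        ix + 2 > gx - 1 || iy + 2 > gy - 1 || iz + 2 > gz - 1)
      continue;
    double wx[4], wy[4], wz[4];
    for (int a = 0; a < 4; ++a) {
      wx[a] = beta3(x - (ix - 1 + a));
      wy[a] = beta3(y - (iy - 1 + a));
      wz[a] = beta3(z - (iz - 1 + a));
    }
    double ux = 0, uy = 0, uz = 0;
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wyz;
          if (w == 0) continue;
          R_xlen_t id = lin(ix - 1 + a, iy - 1 + b, iz - 1 + c, gx, gy);
          ux += w * coef(id, 0);
          uy += w * coef(id, 1);
          uz += w * coef(id, 2);
        }
      }
    }
    out(p, 0) = ux; out(p, 1) = uy; out(p, 2) = uz;
  }
  return out;
}

// Scatter-add of per-sample metric derivatives onto control-point parameters.
// dvals: N x 3 with dvals(i, k) = dMetric/dm_i * dI_M/dy_k at sample i; the
// gradient w.r.t. coef(j, k) is sum_i w_j(x_i) * dvals(i, k).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_param_grad(IntegerVector gdim, NumericMatrix pts,
                                     NumericMatrix dvals) {
  const int gx = gdim[0], gy = gdim[1], gz = gdim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix grad((R_xlen_t)gx * gy * gz, 3);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix - 1 < 0 || iy - 1 < 0 || iz - 1 < 0 ||
        ix + 2 > gx - 1 || iy + 2 > gy - 1 || iz + 2 > gz - 1)
      continue;
    double wx[4], wy[4], wz[4];
    for (int a = 0; a < 4; ++a) {
      wx[a] = beta3(x - (ix - 1 + a));
      wy[a] = beta3(y - (iy - 1 + a));
      wz[a] = beta3(z - (iz - 1 + a));
    }
    double d0 = dvals(p, 0), d1 = dvals(p, 1), d2 = dvals(p, 2);
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wyz;
          if (w == 0) continue;
          R_xlen_t id = lin(ix - 1 + a, iy - 1 + b, iz - 1 + c, gx, gy);
          grad(id, 0) += w * d0;
          grad(id, 1) += w * d1;
          grad(id, 2) += w * d2;
        }
      }
    }
  }
  return grad;
}
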