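#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear index into an array of dim (nx, ny, nz), 0-based voxel indices.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// pts: N x 3 matrix (x, y, z). The half-voxel border band is treated as
// inside (coordinates clamp to the edge, as in ITK's linear interpolator);
// points beyond [-0.5, n-0.5] on any axis get `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5 ||
        !std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
      out[p] = fill;
      continue;
    }
    x = std::max(0.0, std::min(x, (double)(nx - 1)));
    y = std::max(0.0, std::min(y, (double)(ny - 1)));
    z = std::max(0.0, std::min(z, (double)(nz - 1)));
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = v[lin(i0, j0, k0, nx, ny)], c100 = v[lin(i1, j0, k0, nx, ny)];
    double c010 = v[lin(i0, j1, k0, nx, ny)], c110 = v[lin(i1, j1, k0, nx, ny)];
    double c001 = v[lin(i0, j0, k1, nx, ny)], c101 = v[lin(i1, j0, k1, nx, ny)];
    double c011 = v[lin(i0, j1, k1, nx, ny)], c111 = v[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Trilinear interpolation with spatial gradient (in index units) and an
// inside-domain flag. Outside points: value = fill, gradient = 0.
// [[Rcpp::export]]
List cpp_interp3_grad(NumericVector vol, IntegerVector dim,
                      NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);
  LogicalVector inside(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5 ||
        !std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
      val[p] = fill;
      inside[p] = false;
      continue;
    }
    inside[p] = true;
    x = std::max(0.0, std::min(x, (double)(nx - 1)));
    y = std::max(0.0, std::min(y, (double)(ny - 1)));
    z = std::max(0.0, std::min(z, (double)(nz - 1)));
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 >= nx - 1) i0 = nx - 2;
    if (j0 >= ny - 1) j0 = ny - 2;
    if (k0 >= nz - 1) k0 = nz - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = v[lin(i0, j0, k0, nx, ny)], c100 = v[lin(i1, j0, k0, nx, ny)];
    double c010 = v[lin(i0, j1, k0, nx, ny)], c110 = v[lin(i1, j1, k0, nx, ny)];
    double c001 = v[lin(i0, j0, k1, nx, ny)], c101 = v[lin(i1, j0, k1, nx, ny)];
    double c011 = v[lin(i0, j1, k1, nx, ny)], c111 = v[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    val[p] = c0 * (1 - fz) + c1 * fz;
    // d/dx
    double dx00 = c100 - c000, dx10 = c110 - c010;
    double dx01 = c101 - c001, dx11 = c111 - c011;
    double dx0 = dx00 * (1 - fy) + dx10 * fy;
    double dx1 = dx01 * (1 - fy) + dx11 * fy;
    grad(p, 0) = dx0 * (1 - fz) + dx1 * fz;
    // d/dy
    double dy0 = c10 - c00, dy1 = c11 - c01;
    grad(p, 1) = dy0 * (1 - fz) + dy1 * fz;
    // d/dz
    grad(p, 2) = c1 - c0;
  }
  return List::create(_["value"] = val, _["grad"] = grad, _["inside"] = inside);
}

// Nearest-neighbour interpolation at continuous 0-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_interp3_nearest(NumericVector vol, IntegerVector dim,
                                  NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5 ||
        !std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
      out[p] = fill;
      continue;
    }
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    i = std::max(0, std::min(i, nx - 1));
    j = std::max(0, std::min(j, ny - 1));
    k = std::max(0, std::min(k, nz - 1));
    out[p] = v[lin(i, j, k, nx, ny)];
  }
  return out;
}
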