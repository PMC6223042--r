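#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Offsets of a discrete ball of radius r (voxels).
static std::vector<std::array<int, 3>> ball_offsets(int r) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r)
          off.push_back({dx, dy, dz});
  return off;
}

// Binary dilation (dilate = TRUE) or erosion with a ball structuring element.
// Out-of-bounds voxels count as background for dilation and as foreground
// for erosion, so a closing does not eat objects touching the volume faces.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, int r,
                        bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  auto off = ball_offsets(r);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = !dilate;
        for (auto &o : off) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          bool v = !dilate;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            v = mask[lin(ii, jj, kk, nx, ny)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[lin(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// Largest 6-connected foreground component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int nlab = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        if (!mask[id] || lab[id]) continue;
        ++nlab;
        R_xlen_t size = 0;
        std::queue<std::array<int, 3>> q;
        q.push({i, j, k});
        lab[id] = nlab;
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          ++size;
          for (int d = 0; d < 6; ++d) {
            int ii = c[0] + dx[d], jj = c[1] + dy[d], kk = c[2] + dz[d];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t nid = lin(ii, jj, kk, nx, ny);
            if (mask[nid] && !lab[nid]) { lab[nid] = nlab; q.push({ii, jj, kk}); }
          }
        }
        if (size > best_size) { best_size = size; best_lab = nlab; }
      }
  LogicalVector out(n);
  for (R_xlen_t id = 0; id < n; ++id) out[id] = (lab[id] == best_lab);
  return out;
}

// Fill interior holes: background voxels not 6-connected to the volume
// border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::queue<std::array<int, 3>> q;
  auto seed = [&](int i, int j, int k) {
    R_xlen_t id = lin(i, j, k, nx, ny);
    if (!mask[id] && !outside[id]) { outside[id] = 1; q.push({i, j, k}); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { seed(i, j, 0); seed(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { seed(i, 0, k); seed(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { seed(0, j, k); seed(nx - 1, j, k); }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    for (int d = 0; d < 6; ++d) {
      int ii = c[0] + dx[d], jj = c[1] + dy[d], kk = c[2] + dz[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t id = lin(ii, jj, kk, nx, ny);
      if (!mask[id] && !outside[id]) { outside[id] = 1; q.push({ii, jj, kk}); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t id = 0; id < n; ++id) out[id] = mask[id] || !outside[id];
  return out;
}
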