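#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
//
// 1D transform of a sampled function f; result d[i] = min_j (i-j)^2 + f[j].
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    if (f[v[k]] == INF) d[q] = INF;
    else d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// set (TRUE) voxel of a 3D logical raster. Voxels of an all-FALSE raster get Inf.
// [[Rcpp::export(name = ".sq_edt3d")]]
NumericVector sq_edt3d(LogicalVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;
  // index helper: column-major, idx = x + nx*(y + ny*z)
  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
    }
  return out;
}

// ---- connected component labelling ----
//
// Labels connected TRUE voxels of a 2D (nz == 1) or 3D logical raster.
// connectivity: 4 or 8 in 2D (within the x-y plane), 6 or 26 in 3D.
// Labels are assigned in increasing order of the first (column-major) voxel
// of each component, starting at 1; background is 0.
// [[Rcpp::export(name = ".label_cc")]]
IntegerVector label_cc(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        bool use = false;
        if (connectivity == 4)  use = (dz == 0 && manh == 1);
        else if (connectivity == 8)  use = (dz == 0);
        else if (connectivity == 6)  use = (manh == 1);
        else if (connectivity == 26) use = true;
        if (use) { offx.push_back(dx); offy.push_back(dy); offz.push_back(dz); }
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offx.size(); ++k) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
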