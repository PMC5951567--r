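#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Linear index helpers for column-major (x fastest) 3D grids, 0-based.
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 6-connected flood fill of voxels with value in [lo_hu, hi_hu], restricted to
// the axis-aligned box [lo, hi] (inclusive, 0-based voxel indices).
// [[Rcpp::export(name = ".cpp_flood_fill6")]]
LogicalVector cpp_flood_fill6(NumericVector vol, IntegerVector dim,
                              IntegerVector seed, IntegerVector lo,
                              IntegerVector hi, double lo_hu, double hi_hu) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(vol.size(), false);
  std::queue<int> q;
  const int s = lin(seed[0], seed[1], seed[2], nx, ny);
  const double v0 = vol[s];
  if (v0 < lo_hu || v0 > hi_hu) return out;
  out[s] = true;
  q.push(s);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int c = q.front(); q.pop();
    int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < lo[0] || ii > hi[0] || jj < lo[1] || jj > hi[1] ||
          kk < lo[2] || kk > hi[2]) continue;
      int n = lin(ii, jj, kk, nx, ny);
      if (out[n]) continue;
      double v = vol[n];
      if (v >= lo_hu && v <= hi_hu) { out[n] = true; q.push(n); }
    }
  }
  return out;
}

// Label 6-connected components of a binary grid. Labels start at 1; 0 is
// background. Returns an integer grid.
// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  std::queue<int> q;
  for (int start = 0; start < mask.size(); ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int i = c % nx, j = (c / nx) % ny, k = c / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int n = lin(ii, jj, kk, nx, ny);
        if (mask[n] && !lab[n]) { lab[n] = next; q.push(n); }
      }
    }
  }
  return lab;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher),
// sample spacing w (mm). f holds squared distances; overwritten in place.
static void dt1d(std::vector<double>& f, double w) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean squared distance (mm^2) from every voxel to the nearest
// mask voxel, on an anisotropic grid.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: true infinity breaks the parabola intersection
  // arithmetic (inf - inf)
  const double INF = 1e20;
  NumericVector g(mask.size());
  for (int i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : INF;
  std::vector<double> buf;
  // pass along x
  buf.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) buf[i] = g[lin(i, j, k, nx, ny)];
      dt1d(buf, spacing[0]);
      for (int i = 0; i < nx; ++i) g[lin(i, j, k, nx, ny)] = buf[i];
    }
  // pass along y
  buf.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) buf[j] = g[lin(i, j, k, nx, ny)];
      dt1d(buf, spacing[1]);
      for (int j = 0; j < ny; ++j) g[lin(i, j, k, nx, ny)] = buf[j];
    }
  // pass along z
  buf.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) buf[k] = g[lin(i, j, k, nx, ny)];
      dt1d(buf, spacing[2]);
      for (int k = 0; k < nz; ++k) g[lin(i, j, k, nx, ny)] = buf[k];
    }
  return g;
}

// Mean over an axis-aligned box window (2*r+1 voxels per axis, edge-clipped)
// via a summed-area table. Used for patch descriptors and local-SD maps.
// [[Rcpp::export(name = ".cpp_box_mean3")]]
NumericVector cpp_box_mean3(NumericVector vol, IntegerVector dim,
                            IntegerVector radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int rx = radius[0], ry = radius[1], rz = radius[2];
  // summed-area table with one layer of zero padding
  const int sx = nx + 1, sy = ny + 1, sz = nz + 1;
  std::vector<double> S((size_t)sx * sy * sz, 0.0);
  auto sidx = [sx, sy](int i, int j, int k) {
    return (size_t)i + (size_t)sx * ((size_t)j + (size_t)sy * k);
  };
  for (int k = 1; k < sz; ++k)
    for (int j = 1; j < sy; ++j)
      for (int i = 1; i < sx; ++i) {
        S[sidx(i, j, k)] = vol[lin(i - 1, j - 1, k - 1, nx, ny)]
          + S[sidx(i - 1, j, k)] + S[sidx(i, j - 1, k)] + S[sidx(i, j, k - 1)]
          - S[sidx(i - 1, j - 1, k)] - S[sidx(i - 1, j, k - 1)]
          - S[sidx(i, j - 1, k - 1)] + S[sidx(i - 1, j - 1, k - 1)];
      }
  NumericVector out(vol.size());
  for (int k = 0; k < nz; ++k) {
    int k0 = std::max(0, k - rz), k1 = std::min(nz - 1, k + rz);
    for (int j = 0; j < ny; ++j) {
      int j0 = std::max(0, j - ry), j1 = std::min(ny - 1, j + ry);
      for (int i = 0; i < nx; ++i) {
        int i0 = std::max(0, i - rx), i1 = std::min(nx - 1, i + rx);
        double s = S[sidx(i1 + 1, j1 + 1, k1 + 1)]
          - S[sidx(i0, j1 + 1, k1 + 1)] - S[sidx(i1 + 1, j0, k1 + 1)]
          - S[sidx(i1 + 1, j1 + 1, k0)] + S[sidx(i0, j0, k1 + 1)]
          + S[sidx(i0, j1 + 1, k0)] + S[sidx(i1 + 1, j0, k0)]
          - S[sidx(i0, j0, k0)];
        double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1) * (k1 - k0 + 1);
        out[lin(i, j, k, nx, ny)] = s / n;
      }
    }
  }
  return out;
}
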