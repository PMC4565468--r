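#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared distance transform of sampled function f (Felzenszwalh &
// Huttenlocher lower-envelope algorithm); sample q sits at position q*h mm.
static void dt1d(const double *f, double *d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * h, s;
    while (true) {
      double xp = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact squared Euclidean distance transform of a binary mask (distance of
// foreground voxels to nearest background voxel), anisotropic spacing in mm.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f.data(), d.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return out;
}

// Connected-component labeling of a binary mask, 6-connectivity (3D) when
// dim[2] > 1, 4-connectivity per slice otherwise. Labels are 1..K in
// decreasing-size-agnostic scan order; 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, bool connect_z) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx);
      int y = (int)((p / nx) % ny);
      int z = (int)(p / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      int nn = connect_z ? 6 : 4;
      for (int t = 0; t < nn; ++t) {
        int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Region growing by breadth-first search from seed voxels: include neighbors
// whose intensity lies within [lo, hi]. 6-connectivity.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, IntegerVector dim,
                              IntegerVector seeds, double lo, double hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::queue<R_xlen_t> q;
  for (int i = 0; i < seeds.size(); ++i) {
    R_xlen_t s = seeds[i] - 1; // R 1-based
    if (s < 0 || s >= n) stop("seed index out of range");
    if (!out[s] && img[s] >= lo && img[s] <= hi) { out[s] = true; q.push(s); }
  }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    R_xlen_t p = q.front(); q.pop();
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t pq = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!out[pq] && img[pq] >= lo && img[pq] <= hi) { out[pq] = true; q.push(pq); }
    }
  }
  return out;
}
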