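// Voxel-grid primitives for the synthetic-arch pipeline: tube
// rasterization (union of spheres along a dense centerline), an exact
// Euclidean distance transform (Felzenszwalb & Huttenlocher's separable
// lower-envelope algorithm, generalised to anisotropic spacing), and
// 6-connected component labelling.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// [[Rcpp::export]]
IntegerVector cpp_voxelize_tube(NumericMatrix pts, NumericVector radii,
                                IntegerVector dim, NumericVector origin,
                                NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int p = 0; p < pts.nrow(); ++p) {
    const double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    const double r = radii[p];
    if (r <= 0) continue;
    const double r2 = r * r;
    int i0 = std::max(0, (int)std::floor((cx - r - origin[0]) / sx));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + r - origin[0]) / sx));
    int j0 = std::max(0, (int)std::floor((cy - r - origin[1]) / sy));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + r - origin[1]) / sy));
    int k0 = std::max(0, (int)std::floor((cz - r - origin[2]) / sz));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + r - origin[2]) / sz));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * sz - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * sy - cy;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * sx - cx;
          if (dx * dx + dyz <= r2) out[idx3(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }
  return out;
}

// 1D squared-distance transform over samples at positions x (lower envelope
// of parabolas), after Felzenszwalb & Huttenlocher.
static void dt1d(const std::vector<double>& f, const std::vector<double>& x,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      if (f[p] == INF) { // first finite parabola
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
        --k; continue;
      }
      s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
          (2 * x[q] - 2 * x[p]);
      if (s <= z[k]) { --k; continue; }
      break;
    }
    if (v[k] != q) { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < x[q]) ++kk;
    int p = v[kk];
    d[q] = (f[p] == INF) ? INF : (x[q] - x[p]) * (x[q] - x[p]) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t)
    g[t] = mask[t] ? INF : 0.0;

  std::vector<double> f, x, d;
  // pass along x
  f.resize(nx); x.resize(nx); d.resize(nx);
  for (int i = 0; i < nx; ++i) x[i] = i * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, x, d);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); x.resize(ny); d.resize(ny);
  for (int j = 0; j < ny; ++j) x[j] = j * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, x, d);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); x.resize(nz); d.resize(nz);
  for (int k = 0; k < nz; ++k) x[k] = k * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, x, d);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }
  NumericVector out(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t)
    out[t] = std::sqrt(g[t]);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_components6(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<R_xlen_t> q;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = idx3(i, j, k, nx, ny);
        if (!mask[t] || lab[t]) continue;
        lab[t] = ++next;
        q.push(t);
        while (!q.empty()) {
          R_xlen_t u = q.front(); q.pop();
          int ui = (int)(u % nx);
          int uj = (int)((u / nx) % ny);
          int uk = (int)(u / ((R_xlen_t)nx * ny));
          for (int m = 0; m < 6; ++m) {
            int vi = ui + di[m], vj = uj + dj[m], vk = uk + dk[m];
            if (vi < 0 || vi >= nx || vj < 0 || vj >= ny ||
                vk < 0 || vk >= nz) continue;
            R_xlen_t v = idx3(vi, vj, vk, nx, ny);
            if (mask[v] && !lab[v]) { lab[v] = next; q.push(v); }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}
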