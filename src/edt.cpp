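#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance transform,
// generalised to anisotropic grids by scaling each axis by its spacing.
// f holds squared distances; w is the voxel spacing along this axis (mm).
static void dt1d(const std::vector<double>& f, double w,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      if (f[v[k]] == INF) { s = -INF; break; }
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) d[(size_t)i] = mask[i] ? INF : 0.0;

  std::vector<double> f, g;
  // pass along x (fastest-varying index)
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, spacing[0], g);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (size_t)y * nx];
      dt1d(f, spacing[1], g);
      for (int y = 0; y < ny; ++y) d[base + (size_t)y * nx] = g[y];
    }
  // pass along z
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = d[base + (size_t)z * nx * ny];
      dt1d(f, spacing[2], g);
      for (int z = 0; z < nz; ++z) d[base + (size_t)z * nx * ny] = g[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[(size_t)i]);
  return out;
}
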