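#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb-Huttenlocher 1-D squared distance transform of a sampled
// function f at grid positions i*s (s = spacing along this axis).
// Exact: returned values are sums of w*(i-q)^2 terms plus the source f,
// so with integer-representable w they carry no envelope rounding.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + w * q * (double)q) - (f[v[k]] + w * v[k] * (double)v[k])) /
               (2.0 * w * (q - v[k]));
    while (s <= z[k]) {
      k--;
      if (f[v[k]] == INF) { s = -INF; break; }
      s = ((f[q] + w * q * (double)q) - (f[v[k]] + w * v[k] * (double)v[k])) /
          (2.0 * w * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    if (f[v[k]] == INF) { d[q] = INF; continue; }
    double dq = (double)(q - v[k]);
    d[q] = w * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  double w = spacing[0] * spacing[0];
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, w);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  w = spacing[1] * spacing[1];
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, w);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  w = spacing[2] * spacing[2];
  R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * slab];
      dt1d(f, d, v, z, nz, w);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * slab] = d[k];
    }
  return out;
}

// 26-connectivity labeling of a 3-D logical array, BFS flood fill.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    cur++;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int px = (int)(p % nx);
      int py = (int)((p / nx) % ny);
      int pz = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int qx = px + dx, qy = py + dy, qz = pz + dz;
            if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx;
            if (mask[q] == TRUE && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}
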