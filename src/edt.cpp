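#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower-envelope algorithm of
// Felzenszwalb & Huttenlocher) at arbitrary sample positions p[i] = i*h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double pq = q * h;
    double s;
    while (true) {
      double pv = v[k] * h;
      s = ((f[q] + pq * pq) - (f[v[k]] + pv * pv)) / (2.0 * pq - 2.0 * pv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double pq = q * h;
    while (z[k + 1] < pq) ++k;
    double dp = pq - v[k] * h;
    d[q] = dp * dp + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of infinity: the lower-envelope update
  // computes differences of f values, and inf - inf would poison the scan
  const double INF = 1e15;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // axis 0 (fastest varying)
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0], nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // axis 1
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, spacing[1], ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // axis 2
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, spacing[2], nz);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = out[i] >= 1e14 ? R_PosInf : std::sqrt(out[i]);
  return out;
}
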