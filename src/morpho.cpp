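#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_max_pairwise")]]
double cpp_max_pairwise(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_convolve_axis")]]
NumericVector cpp_convolve_axis(NumericVector field, IntegerVector dims,
                                NumericVector kernel, int axis) {
  // zero-boundary separable convolution along `axis` (0-based), centred
  // odd-length kernel
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int klen = kernel.size();
  const int kr = (klen - 1) / 2;
  NumericVector out(n, 0.0);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = nd[axis];
  const R_xlen_t sa = stride[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int pos[3] = {i, j, k};
        if (pos[axis] != 0) continue; // iterate lines once
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        for (int p = 0; p < na; ++p) {
          double acc = 0.0;
          int lo = std::max(0, p - kr), hi = std::min(na - 1, p + kr);
          for (int q = lo; q <= hi; ++q)
            acc += field[base + (R_xlen_t)q * sa] * kernel[kr + (p - q)];
          out[base + (R_xlen_t)p * sa] = acc;
        }
      }
  return out;
}
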