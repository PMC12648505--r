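#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx); 0-based linear index
// i = z + nz * (y + ny * x).  Connectivity: 6 (faces), 18 (+edges), 26 (+corners).

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n);

  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dz, dy, dx});
      }

  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p % nz);
      R_xlen_t r = p / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (const auto &o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
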