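#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// dim = c(nz, ny, nx); index i = z + nz*(y + ny*x).
// All filters renormalize truncated windows at the borders, so constant
// volumes map to constant volumes exactly.

static void gauss_axis(const std::vector<double> &src, std::vector<double> &dst,
                       int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int j = -r; j <= r; ++j)
    k[j + r] = std::exp(-0.5 * (double)j * j / (sigma * sigma));
  const R_xlen_t sz = (R_xlen_t)nz * ny * nx;
  (void)sz;
  int n_axis = axis == 0 ? nz : (axis == 1 ? ny : nx);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nz : (R_xlen_t)nz * ny);
  // iterate over all lines along `axis`
  for (int a = 0; a < (axis == 0 ? ny : nz); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
      else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
      else base = a + (R_xlen_t)nz * b;
      for (int i = 0; i < n_axis; ++i) {
        double s = 0, w = 0;
        int j0 = std::max(-r, -i), j1 = std::min(r, n_axis - 1 - i);
        for (int j = j0; j <= j1; ++j) {
          double kk = k[j + r];
          s += kk * src[base + (R_xlen_t)(i + j) * stride];
          w += kk;
        }
        dst[base + (R_xlen_t)i * stride] = s / w;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  gauss_axis(a, b, nz, ny, nx, 0, sigma[0]);
  gauss_axis(b, a, nz, ny, nx, 1, sigma[1]);
  gauss_axis(a, b, nz, ny, nx, 2, sigma[2]);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

static void boxmean_axis(const std::vector<double> &src,
                         std::vector<double> &dst, int nz, int ny, int nx,
                         int axis, int r) {
  if (r <= 0) { dst = src; return; }
  int n_axis = axis == 0 ? nz : (axis == 1 ? ny : nx);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nz : (R_xlen_t)nz * ny);
  std::vector<double> pref(n_axis + 1);
  for (int a = 0; a < (axis == 0 ? ny : nz); ++a)
    for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
      else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
      else base = a + (R_xlen_t)nz * b;
      pref[0] = 0;
      for (int i = 0; i < n_axis; ++i)
        pref[i + 1] = pref[i] + src[base + (R_xlen_t)i * stride];
      for (int i = 0; i < n_axis; ++i) {
        int lo = std::max(0, i - r), hi = std::min(n_axis - 1, i + r);
        dst[base + (R_xlen_t)i * stride] =
            (pref[hi + 1] - pref[lo]) / (double)(hi - lo + 1);
      }
    }
}

// Mean over the intersection of a (2r+1)^3 box with the volume (truncated at
// borders).  Per-axis truncated means compose exactly to the box mean.
// [[Rcpp::export]]
NumericVector cpp_boxmean3d(NumericVector vol, IntegerVector dim,
                            IntegerVector r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  boxmean_axis(a, b, nz, ny, nx, 0, r[0]);
  boxmean_axis(b, a, nz, ny, nx, 1, r[1]);
  boxmean_axis(a, b, nz, ny, nx, 2, r[2]);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// in-place truncated box-mean passes on a sub-grid held in buf (a/b swap)
static void boxmean3_buf(std::vector<double> &a, std::vector<double> &b,
                         int snz, int sny, int snx, int r) {
  boxmean_axis(a, b, snz, sny, snx, 0, r);
  boxmean_axis(b, a, snz, sny, snx, 1, r);
  boxmean_axis(a, b, snz, sny, snx, 2, r);
  std::swap(a, b);  // result in a
}

// Non-local means, offset-decomposed: for every search offset t the patch
// distance D(i) = mean over the patch of (I(i+p) - I(i+t+p))^2 is computed
// with separable box sums on the valid overlap region, then weights
// w = exp(-max(D - 2*sigma^2, 0) / h^2) accumulate I(i+t) (the 2*sigma^2
// term removes the noise bias of the patch distance, as in Buades' method).
// The center voxel enters with w = 1.
// [[Rcpp::export]]
NumericVector cpp_nlm3d(NumericVector vol, IntegerVector dim, int patch_r,
                        int search_r, double h, double sigma = 0.0) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (!(h > 0) || !std::isfinite(h)) stop("h must be finite and > 0");
  if (patch_r < 1 || search_r < 1) stop("radii must be >= 1");
  std::vector<double> acc(n), wsum(n), d(n), scratch(n);
  const double *v = REAL(vol);
  const double inv_h2 = 1.0 / (h * h);
  const double bias = 2.0 * sigma * sigma;

  for (R_xlen_t i = 0; i < n; ++i) { acc[i] = v[i]; wsum[i] = 1.0; }

  for (int tx = -search_r; tx <= search_r; ++tx)
    for (int ty = -search_r; ty <= search_r; ++ty)
      for (int tz = -search_r; tz <= search_r; ++tz) {
        if (!tx && !ty && !tz) continue;
        R_xlen_t toff = tz + (R_xlen_t)nz * (ty + (R_xlen_t)ny * tx);
        int z0 = std::max(0, -tz), z1 = nz - 1 - std::max(0, tz);
        int y0 = std::max(0, -ty), y1 = ny - 1 - std::max(0, ty);
        int x0 = std::max(0, -tx), x1 = nx - 1 - std::max(0, tx);
        if (z1 < z0 || y1 < y0 || x1 < x0) continue;
        int snz = z1 - z0 + 1, sny = y1 - y0 + 1, snx = x1 - x0 + 1;
        // squared differences on the valid sub-grid
        R_xlen_t k = 0;
        for (int x = x0; x <= x1; ++x)
          for (int y = y0; y <= y1; ++y) {
            R_xlen_t b = z0 + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            for (int z = 0; z < snz; ++z, ++k) {
              double df = v[b + z] - v[b + z + toff];
              d[k] = df * df;
            }
          }
        boxmean3_buf(d, scratch, snz, sny, snx, patch_r);
        k = 0;
        for (int x = x0; x <= x1; ++x)
          for (int y = y0; y <= y1; ++y) {
            R_xlen_t b = z0 + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            for (int z = 0; z < snz; ++z, ++k) {
              double excess = d[k] - bias;
              double w = excess <= 0 ? 1.0 : std::exp(-excess * inv_h2);
              acc[b + z] += w * v[b + z + toff];
              wsum[b + z] += w;
            }
          }
      }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = acc[i] / wsum[i];
  out.attr("dim") = dim;
  return out;
}

// Trilinear resampling.  Voxel i (0-based) of a grid with spacing s has its
// center at (i + 0.5) * s; output centers are mapped into input voxel
// coordinates and clamped, so constant volumes stay constant.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector dim,
                                     NumericVector spacing,
                                     IntegerVector out_dim,
                                     NumericVector out_spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int oz = out_dim[0], oy = out_dim[1], ox = out_dim[2];
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)oz * oy * ox);
  std::vector<double> cz(oz), cy(oy), cx(ox);
  std::vector<int> iz(oz), iy(oy), ix(ox);
  auto prep = [](std::vector<double> &f, std::vector<int> &i0, int no,
                 double so, double si, int ni) {
    for (int i = 0; i < no; ++i) {
      double c = ((i + 0.5) * so) / si - 0.5;
      if (c < 0) c = 0;
      if (c > ni - 1) c = ni - 1;
      int j = (int)std::floor(c);
      if (j > ni - 2) j = std::max(0, ni - 2);
      i0[i] = j;
      f[i] = ni == 1 ? 0.0 : c - j;
    }
  };
  prep(cz, iz, oz, out_spacing[0], spacing[0], nz);
  prep(cy, iy, oy, out_spacing[1], spacing[1], ny);
  prep(cx, ix, ox, out_spacing[2], spacing[2], nx);
  R_xlen_t k = 0;
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z, ++k) {
        int z0 = iz[z], y0 = iy[y], x0 = ix[x];
        int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
            x1 = std::min(x0 + 1, nx - 1);
        double fz = cz[z], fy = cy[y], fx = cx[x];
        auto at = [&](int zz, int yy, int xx) {
          return v[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        };
        double c00 = at(z0, y0, x0) * (1 - fz) + at(z1, y0, x0) * fz;
        double c10 = at(z0, y1, x0) * (1 - fz) + at(z1, y1, x0) * fz;
        double c01 = at(z0, y0, x1) * (1 - fz) + at(z1, y0, x1) * fz;
        double c11 = at(z0, y1, x1) * (1 - fz) + at(z1, y1, x1) * fz;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[k] = c0 * (1 - fx) + c1 * fx;
      }
  out.attr("dim") = out_dim;
  return out;
}
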