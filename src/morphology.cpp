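#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grayscale erosion/dilation by an ellipsoidal ball of voxel radii
// (rz, ry, rx): offset (dz,dy,dx) belongs to the structuring element iff
// (dz/rz)^2 + (dy/ry)^2 + (dx/rx)^2 <= 1.  Decomposition: for each in-disc
// (dy,dx) the SE contributes a z-run of half-length h(dy,dx); z-runs are
// min/max-filtered with the van Herk/Gil-Werman algorithm and combined over
// (dy,dx) with a ring buffer of x-slices, keeping memory at
// O((2*rx+1) * n_distinct_h * nz * ny).
// Voxels outside the volume are ignored (identity element), so
// opening(f) <= f holds everywhere.

static void run_extreme(const double *a, double *out, int n, int h, bool mn) {
  const double ident = mn ? std::numeric_limits<double>::infinity()
                          : -std::numeric_limits<double>::infinity();
  if (h <= 0) { std::copy(a, a + n, out); return; }
  int w = 2 * h + 1;
  int np = ((n + h) / w + 1) * w;
  std::vector<double> g(np, ident), f(np, ident);
  for (int i = 0; i < np; ++i) {
    double v = i < n ? a[i] : ident;
    if (i % w == 0) g[i] = v;
    else g[i] = mn ? std::min(g[i - 1], v) : std::max(g[i - 1], v);
  }
  for (int i = np - 1; i >= 0; --i) {
    double v = i < n ? a[i] : ident;
    if (i % w == w - 1 || i == np - 1) f[i] = v;
    else f[i] = mn ? std::min(f[i + 1], v) : std::max(f[i + 1], v);
  }
  for (int i = 0; i < n; ++i) {
    int l = i - h, r = i + h;
    double fl = l >= 0 ? f[l] : ident;
    double gr = g[r];
    out[i] = mn ? std::min(fl, gr) : std::max(fl, gr);
  }
}

// [[Rcpp::export]]
NumericVector cpp_morph_ball(NumericVector vol, IntegerVector dim,
                             IntegerVector rvox, bool erode) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int rz = rvox[0], ry = rvox[1], rx = rvox[2];
  const R_xlen_t slice_n = (R_xlen_t)nz * ny;
  const double *v = REAL(vol);
  const bool mn = erode;
  const double ident = mn ? std::numeric_limits<double>::infinity()
                          : -std::numeric_limits<double>::infinity();

  // offsets (dx, dy) with run half-length h
  struct Off { int dx, dy, h; };
  std::vector<Off> offs;
  std::map<int, int> h_slot;
  for (int dx = -rx; dx <= rx; ++dx)
    for (int dy = -ry; dy <= ry; ++dy) {
      double e = 0;
      if (rx > 0) e += (double)dx * dx / ((double)rx * rx);
      else if (dx != 0) continue;
      if (ry > 0) e += (double)dy * dy / ((double)ry * ry);
      else if (dy != 0) continue;
      if (e > 1.0 + 1e-12) continue;
      int h = (int)std::floor(rz * std::sqrt(std::max(0.0, 1.0 - e)) + 1e-9);
      offs.push_back({dx, dy, h});
      if (!h_slot.count(h)) { int s = (int)h_slot.size(); h_slot[h] = s; }
    }
  const int nh = (int)h_slot.size();
  const int nring = 2 * rx + 1;

  // ring buffer: z-run-filtered versions of input x-slices
  std::vector<std::vector<double>> cache((R_xlen_t)nring * nh);
  for (auto &c : cache) c.assign(slice_n, ident);
  std::vector<int> cached_x(nring, -2);

  NumericVector out((R_xlen_t)nz * ny * nx);
  std::vector<double> col(nz);

  auto load_slice = [&](int xs) {
    int slot = ((xs % nring) + nring) % nring;
    if (cached_x[slot] == xs) return;
    cached_x[slot] = xs;
    const double *src = v + (R_xlen_t)slice_n * xs;
    for (auto &hs : h_slot) {
      std::vector<double> &dst = cache[(R_xlen_t)slot * nh + hs.second];
      for (int y = 0; y < ny; ++y)
        run_extreme(src + (R_xlen_t)nz * y, dst.data() + (R_xlen_t)nz * y,
                    nz, hs.first, mn);
    }
  };

  for (int x = 0; x < nx; ++x) {
    for (int xs = std::max(0, x - rx); xs <= std::min(nx - 1, x + rx); ++xs)
      load_slice(xs);
    double *o = REAL(out) + (R_xlen_t)slice_n * x;
    for (R_xlen_t i = 0; i < slice_n; ++i) o[i] = ident;
    for (const auto &of : offs) {
      int xx = x + of.dx;
      if (xx < 0 || xx >= nx) continue;
      int slot = xx % nring;
      const double *c = cache[(R_xlen_t)slot * nh + h_slot[of.h]].data();
      int y0 = std::max(0, -of.dy), y1 = ny - 1 - std::max(0, of.dy);
      for (int y = y0; y <= y1; ++y) {
        double *orow = o + (R_xlen_t)nz * y;
        const double *crow = c + (R_xlen_t)nz * (y + of.dy);
        if (mn)
          for (int z = 0; z < nz; ++z)
            if (crow[z] < orow[z]) orow[z] = crow[z];
        if (!mn)
          for (int z = 0; z < nz; ++z)
            if (crow[z] > orow[z]) orow[z] = crow[z];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
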