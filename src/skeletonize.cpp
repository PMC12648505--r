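#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Homotopic curve thinning for (26, 6) digital topology.
// A foreground voxel is "simple" (deletable without changing topology) iff
//   (a) its 26-neighborhood foreground forms exactly one 26-connected
//       component, and
//   (b) the background within its 18-neighborhood forms exactly one
//       6-connected component that touches a face neighbor
// (Bertrand & Malandain characterization).  Simple, non-endpoint border
// voxels are deleted sequentially (re-checking at deletion time, which makes
// topology preservation unconditional) in six directional sub-cycles with a
// fixed raster order, giving a deterministic, one-voxel-wide curve skeleton
// with endpoints preserved.

namespace {

bool tables_ready = false;
int off_d[27][3];              // (dz,dy,dx) of neighborhood cell k
bool adj26[27][27];
bool adj6[27][27];
bool in_n18[27];
bool is_face[27];

void init_tables() {
  if (tables_ready) return;
  for (int k = 0; k < 27; ++k) {
    off_d[k][0] = k % 3 - 1;
    off_d[k][1] = (k / 3) % 3 - 1;
    off_d[k][2] = k / 9 - 1;
    int m = std::abs(off_d[k][0]) + std::abs(off_d[k][1]) + std::abs(off_d[k][2]);
    in_n18[k] = (k != 13) && m <= 2;
    is_face[k] = m == 1;
  }
  for (int a = 0; a < 27; ++a)
    for (int b = 0; b < 27; ++b) {
      int dz = std::abs(off_d[a][0] - off_d[b][0]);
      int dy = std::abs(off_d[a][1] - off_d[b][1]);
      int dx = std::abs(off_d[a][2] - off_d[b][2]);
      adj26[a][b] = (a != b) && dz <= 1 && dy <= 1 && dx <= 1;
      adj6[a][b] = (dz + dy + dx) == 1;
    }
  tables_ready = true;
}

// number of 26-CCs of foreground among the 26 neighbors
int fg_cc26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncc = 0;
  int stack[27], sp;
  for (int k = 0; k < 27; ++k) {
    if (k == 13 || !nb[k] || seen[k]) continue;
    ++ncc;
    sp = 0;
    stack[sp++] = k;
    seen[k] = true;
    while (sp) {
      int p = stack[--sp];
      for (int q = 0; q < 27; ++q)
        if (q != 13 && nb[q] && !seen[q] && adj26[p][q]) {
          seen[q] = true;
          stack[sp++] = q;
        }
    }
  }
  return ncc;
}

// number of 6-CCs of background within N18 that contain a face neighbor
int bg_cc6_n18(const bool nb[27]) {
  bool seen[27] = {false};
  int ncc = 0;
  int stack[27], sp;
  for (int s = 0; s < 27; ++s) {
    if (!is_face[s] || nb[s] || seen[s]) continue;
    ++ncc;
    sp = 0;
    stack[sp++] = s;
    seen[s] = true;
    while (sp) {
      int p = stack[--sp];
      for (int q = 0; q < 27; ++q)
        if (in_n18[q] && !nb[q] && !seen[q] && adj6[p][q]) {
          seen[q] = true;
          stack[sp++] = q;
        }
    }
  }
  return ncc;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_skeletonize3d(LogicalVector mask, IntegerVector dim, int max_cycles = 0) {
  init_tables();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> fg(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  R_xlen_t noff[27];
  for (int k = 0; k < 27; ++k)
    noff[k] = off_d[k][0] + (R_xlen_t)nz * (off_d[k][1] + (R_xlen_t)ny * off_d[k][2]);

  auto gather = [&](R_xlen_t p, int z, int y, int x, bool nb[27]) {
    for (int k = 0; k < 27; ++k) {
      int zz = z + off_d[k][0], yy = y + off_d[k][1], xx = x + off_d[k][2];
      nb[k] = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
                  ? fg[p + noff[k]] != 0
                  : false;
    }
  };
  auto coords = [&](R_xlen_t p, int &z, int &y, int &x) {
    z = (int)(p % nz);
    R_xlen_t r = p / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  };
  auto fg_nb_count = [](const bool nb[27]) {
    int c = 0;
    for (int k = 0; k < 27; ++k)
      if (k != 13 && nb[k]) ++c;
    return c;
  };

  // directions: -z, +z, -y, +y, -x, +x as neighborhood cell indices
  const int dir_cell[6] = {12, 14, 10, 16, 4, 22};

  // initial candidate list: foreground voxels with a 6-background neighbor
  std::vector<R_xlen_t> cand;
  std::vector<unsigned char> in_list(n, 0);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!fg[p]) continue;
    int z, y, x;
    coords(p, z, y, x);
    bool border = false;
    for (int d = 0; d < 6 && !border; ++d) {
      int k = dir_cell[d];
      int zz = z + off_d[k][0], yy = y + off_d[k][1], xx = x + off_d[k][2];
      border = (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                   ? true
                   : !fg[p + noff[k]];
    }
    if (border) { cand.push_back(p); in_list[p] = 1; }
  }

  bool nb[27];
  std::vector<R_xlen_t> next;
  int guard = 0;
  while (!cand.empty() && ++guard <= 10000) {
    if (max_cycles > 0 && guard > max_cycles) break;
    std::sort(cand.begin(), cand.end());
    bool deleted_any = false;
    next.clear();
    for (int d = 0; d < 6; ++d) {
      int kd = dir_cell[d];
      // phase 1: voxels that are border in direction d at pass start
      std::vector<R_xlen_t> pass;
      pass.reserve(cand.size());
      for (R_xlen_t p : cand) {
        if (!fg[p]) continue;
        int z, y, x;
        coords(p, z, y, x);
        int zz = z + off_d[kd][0], yy = y + off_d[kd][1], xx = x + off_d[kd][2];
        bool bg_dir =
            (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                ? true
                : !fg[p + noff[kd]];
        if (bg_dir) pass.push_back(p);
      }
      // phase 2: sequential deletion with simplicity re-checked at deletion
      // time (topology-safe), restricted to pass-start border voxels so a
      // single pass cannot cascade through the object
      for (R_xlen_t p : pass) {
        if (!fg[p]) continue;
        int z, y, x;
        coords(p, z, y, x);
        gather(p, z, y, x, nb);
        if (fg_nb_count(nb) <= 1) continue; // endpoint: keep
        if (fg_cc26(nb) != 1 || bg_cc6_n18(nb) != 1) continue;
        fg[p] = 0;
        deleted_any = true;
        for (int k = 0; k < 27; ++k) {
          if (k == 13) continue;
          int z2 = z + off_d[k][0], y2 = y + off_d[k][1], x2 = x + off_d[k][2];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          R_xlen_t q = p + noff[k];
          if (fg[q] && !in_list[q]) { in_list[q] = 1; next.push_back(q); }
        }
      }
    }
    if (!deleted_any) break;
    // next cycle: survivors of the current list plus touched neighbors
    std::vector<R_xlen_t> merged;
    merged.reserve(cand.size() + next.size());
    for (R_xlen_t p : cand)
      if (fg[p]) merged.push_back(p);
      else in_list[p] = 0;
    for (R_xlen_t p : next) merged.push_back(p);
    cand.swap(merged);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
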