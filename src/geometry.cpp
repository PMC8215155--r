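// Grid-based cavity detection and native-contact assignment.
//
// Grids are stored flat with index = ix + nx*(iy + ny*iz).
// Cell labels: 0 = EMPTY, 1 = ATOM, 2 = OUTSIDE, 3 = CAVITY.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + ny * iz);
}

// Mark cells whose center lies within (vdW radius + probe) of any atom.
// coords: m x 3 (grid frame), radii: per-atom vdW radius.
// [[Rcpp::export]]
IntegerVector cpp_rasterize(NumericMatrix coords, NumericVector radii,
                            NumericVector origin, IntegerVector dims,
                            double spacing, double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(nx * ny * nz, 0);
  const int m = coords.nrow();
  for (int a = 0; a < m; ++a) {
    const double R = radii[a] + probe;
    const double R2 = R * R;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    // cell-center coordinates are origin + (i + 0.5) * spacing
    int ix0 = (int)std::floor((ax - R - origin[0]) / spacing - 0.5);
    int ix1 = (int)std::ceil ((ax + R - origin[0]) / spacing - 0.5);
    int iy0 = (int)std::floor((ay - R - origin[1]) / spacing - 0.5);
    int iy1 = (int)std::ceil ((ay + R - origin[1]) / spacing - 0.5);
    int iz0 = (int)std::floor((az - R - origin[2]) / spacing - 0.5);
    int iz1 = (int)std::ceil ((az + R - origin[2]) / spacing - 0.5);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + (iz + 0.5) * spacing - az;
      const double dz2 = dz * dz;
      if (dz2 > R2) continue;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + (iy + 0.5) * spacing - ay;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > R2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + (ix + 0.5) * spacing - ax;
          if (dx * dx + dyz2 <= R2) lab[idx3(ix, iy, iz, nx, ny)] = 1;
        }
      }
    }
  }
  return lab;
}

// Probe rays enter along all six axis directions from outside the grid;
// EMPTY cells swept before the first ATOM cell on each ray become OUTSIDE.
// [[Rcpp::export]]
LogicalVector cpp_ray_sweep(IntegerVector lab, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(nx * ny * nz, false);
  // +x / -x
  for (int iz = 0; iz < nz; ++iz) for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
    for (int ix = nx - 1; ix >= 0; --ix) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
  }
  // +y / -y
  for (int iz = 0; iz < nz; ++iz) for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
    for (int iy = ny - 1; iy >= 0; --iy) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
  }
  // +z / -z
  for (int iy = 0; iy < ny; ++iy) for (int ix = 0; ix < nx; ++ix) {
    for (int iz = 0; iz < nz; ++iz) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
    for (int iz = nz - 1; iz >= 0; --iz) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (lab[k] == 1) break; else out[k] = true;
    }
  }
  return out;
}

// 6-connected flood fill over EMPTY, non-OUTSIDE cells from a seed cell.
// Returns final labels (ATOM/OUTSIDE kept; CAVITY = component of the seed).
// [[Rcpp::export]]
IntegerVector cpp_flood_fill(IntegerVector lab, LogicalVector outside,
                             IntegerVector dims, int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector fin(nx * ny * nz);
  for (int k = 0; k < fin.size(); ++k)
    fin[k] = (lab[k] == 1) ? 1 : (outside[k] ? 2 : 0);
  if (fin[seed] != 0) return fin;  // caller checks seed validity
  std::queue<int> q;
  q.push(seed);
  fin[seed] = 3;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int k = q.front(); q.pop();
    int iz = k / (nx * ny), iy = (k / nx) % ny, ix = k % nx;
    for (int d = 0; d < 6; ++d) {
      int jx = ix + dx[d], jy = iy + dy[d], jz = iz + dz[d];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
        continue;
      int j = idx3(jx, jy, jz, nx, ny);
      if (fin[j] == 0) { fin[j] = 3; q.push(j); }
    }
  }
  return fin;
}

// Count CAVITY cell faces adjacent to an ATOM cell or to an OUTSIDE cell
// that itself touches an ATOM cell (the wetted tunnel surface).
// [[Rcpp::export]]
int cpp_surface_faces(IntegerVector fin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  // OUTSIDE cells adjacent to ATOM
  std::vector<char> oa(fin.size(), 0);
  for (int iz = 0; iz < nz; ++iz) for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (fin[k] != 2) continue;
      for (int d = 0; d < 6; ++d) {
        int jx = ix + dx[d], jy = iy + dy[d], jz = iz + dz[d];
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
          continue;
        if (fin[idx3(jx, jy, jz, nx, ny)] == 1) { oa[k] = 1; break; }
      }
    }
  int faces = 0;
  for (int iz = 0; iz < nz; ++iz) for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      int k = idx3(ix, iy, iz, nx, ny);
      if (fin[k] != 3) continue;
      for (int d = 0; d < 6; ++d) {
        int jx = ix + dx[d], jy = iy + dy[d], jz = iz + dz[d];
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
          continue;
        int j = idx3(jx, jy, jz, nx, ny);
        if (fin[j] == 1 || (fin[j] == 2 && oa[j])) ++faces;
      }
    }
  return faces;
}

// Native contacts by the all-atom overlap criterion: residues i, j
// (|i - j| >= min_sep) are in contact iff some heavy-atom pair satisfies
// r < scale * (vdw_i + vdw_j). Atoms are grouped by residue index.
// [[Rcpp::export]]
DataFrame cpp_overlap_contacts(NumericMatrix atoms, NumericVector vdw,
                               IntegerVector resno, NumericMatrix ca,
                               IntegerVector ca_resno, int min_sep,
                               double scale) {
  const int m = atoms.nrow();
  const int nres = ca.nrow();
  // residue -> atom span (atoms assumed grouped by residue, file order)
  std::vector<int> beg(nres, -1), end(nres, -1);
  std::map<int, int> res_of;  // author residue number -> 0-based model index
  for (int r = 0; r < nres; ++r) res_of[ca_resno[r]] = r;
  for (int a = 0; a < m; ++a) {
    std::map<int, int>::iterator it = res_of.find(resno[a]);
    if (it == res_of.end()) continue;
    int r = it->second;
    if (beg[r] < 0) beg[r] = a;
    end[r] = a;
  }
  double maxvdw = 0;
  for (int a = 0; a < m; ++a) if (vdw[a] > maxvdw) maxvdw = vdw[a];
  const double pre = 25.0 + 2.0 * scale * maxvdw;  // Calpha prefilter (A)
  std::vector<int> ci, cj;
  std::vector<double> rn;
  for (int i = 0; i < nres; ++i) {
    if (beg[i] < 0) continue;
    for (int j = i + min_sep; j < nres; ++j) {
      if (beg[j] < 0) continue;
      double dca2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = ca(i, d) - ca(j, d);
        dca2 += dd * dd;
      }
      if (dca2 > pre * pre) continue;
      bool hit = false;
      for (int a = beg[i]; a <= end[i] && !hit; ++a) {
        for (int b = beg[j]; b <= end[j]; ++b) {
          double cut = scale * (vdw[a] + vdw[b]);
          double d2 = 0;
          for (int d = 0; d < 3; ++d) {
            double dd = atoms(a, d) - atoms(b, d);
            d2 += dd * dd;
          }
          if (d2 < cut * cut) { hit = true; break; }
        }
      }
      if (hit) {
        ci.push_back(i + 1);
        cj.push_back(j + 1);
        rn.push_back(std::sqrt(dca2));
      }
    }
  }
  return DataFrame::create(_["i"] = ci, _["j"] = cj, _["r_nat"] = rn);
}
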