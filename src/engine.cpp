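// Coarse-grained structure-based Langevin engine with sequential growth
// at the PTC. Reduced units: energies in eps, lengths in Angstrom, time
// in tau, unit bead masses, k_B = 1.
//
// Potential terms
//   bonds      V = k (r - d_eq)^2, d_eq ramps 0 -> d0 while a residue emerges
//   chirality  V = kappa/2 * C_i^2 when sign(C_i) != sign(C_i^nat),
//              C_i = [(b_{i-1} x b_i) . b_{i+1}] / d0^3
//   contacts   V = 4 eps [(s/r)^12 - (s/r)^6], s = r_nat 2^{-1/6};
//              "formed" iff r < fold_mult * s
//   non-native/wall-atom repulsion: WCA form with sigma0 = 4 * 2^{-1/6},
//              V = 4 eps [(sigma0/r)^12 - (sigma0/r)^6] + eps for r < 4 A
//   plate      V = amp * eps * (sigma0/z)^wexp applied to every bead
//   mouth      optional eps-deep wells (minimum at 5 A) between charged
//              beads and oppositely charged mouth wall residues

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Params {
  double eps, T, dt, gamma, d0, kbond, kappa, sigma0, repcut,
         wall_amp, wall_exp, fold_mult;
};

struct Model {
  int n;                      // total residues
  std::vector<double> nat;    // native coords, 3n
  std::vector<int> ci, cj;    // native contacts (0-based)
  std::vector<double> sij;    // LJ length per contact
  std::vector<double> cnat;   // native chirality per quadruple (size n-3)
  std::vector<signed char> charge;
  std::vector<signed char> is_contact;  // n*n lookup
  Params p;
  // wall
  bool has_wall = false, has_plate = false, has_mouth = false;
  std::vector<double> wall;   // 3m
  int nwall = 0;
  double mouth_z = R_PosInf;
  std::vector<double> mouth;  // 3k positions of charged mouth residues
  std::vector<signed char> mouth_q;
  // wall cell list
  double cell_side = 4.0, wlo[3], whi[3];
  int ncell[3];
  std::vector<int> chead, cnext;
};

static void build_wall_cells(Model &M) {
  if (!M.has_wall || M.nwall == 0) return;
  for (int d = 0; d < 3; ++d) { M.wlo[d] = R_PosInf; M.whi[d] = R_NegInf; }
  for (int a = 0; a < M.nwall; ++a)
    for (int d = 0; d < 3; ++d) {
      double v = M.wall[3 * a + d];
      if (v < M.wlo[d]) M.wlo[d] = v;
      if (v > M.whi[d]) M.whi[d] = v;
    }
  for (int d = 0; d < 3; ++d) {
    M.ncell[d] = std::max(1, (int)std::ceil((M.whi[d] - M.wlo[d]) / M.cell_side));
  }
  M.chead.assign((size_t)M.ncell[0] * M.ncell[1] * M.ncell[2], -1);
  M.cnext.assign(M.nwall, -1);
  for (int a = 0; a < M.nwall; ++a) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)((M.wall[3 * a + d] - M.wlo[d]) / M.cell_side);
      if (c[d] < 0) c[d] = 0;
      if (c[d] >= M.ncell[d]) c[d] = M.ncell[d] - 1;
    }
    int k = c[0] + M.ncell[0] * (c[1] + M.ncell[1] * c[2]);
    M.cnext[a] = M.chead[k];
    M.chead[k] = a;
  }
}

static inline double chirality(const double *a, const double *b,
                               const double *c, const double *d, double d03,
                               double g[12]) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = b[k] - a[k];
    b2[k] = c[k] - b[k];
    b3[k] = d[k] - c[k];
  }
  double c23[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                   b2[2] * b3[0] - b2[0] * b3[2],
                   b2[0] * b3[1] - b2[1] * b3[0]};
  double c31[3] = {b3[1] * b1[2] - b3[2] * b1[1],
                   b3[2] * b1[0] - b3[0] * b1[2],
                   b3[0] * b1[1] - b3[1] * b1[0]};
  double c12[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                   b1[2] * b2[0] - b1[0] * b2[2],
                   b1[0] * b2[1] - b1[1] * b2[0]};
  double S = b1[0] * c23[0] + b1[1] * c23[1] + b1[2] * c23[2];
  if (g) {
    // dS/dr for the four beads: (-c23, c23 - c31, c31 - c12, c12)
    for (int k = 0; k < 3; ++k) {
      g[k]     = -c23[k];
      g[3 + k] = c23[k] - c31[k];
      g[6 + k] = c31[k] - c12[k];
      g[9 + k] = c12[k];
    }
  }
  return S / d03;
}

struct TermFlags {
  bool bond = true, chir = true, contacts = true, nonnat = true,
       wallatoms = true, plate = true, mouth = false;
};

// Soft-core linearization: below r_sc the diverging 6-12 cores continue
// with constant force (C1-continuous), so violent overlaps created by
// discrete growth events relax instead of blowing up the integrator.
// Equilibrium never visits these separations (the energies there exceed
// hundreds of k_B T).
static const double SC_WCA = 3.0;        // A, for the sigma0 repulsions
static const double SC_CONTACT = 0.84;   // fraction of s_ij
static const double SC_PLATE = 3.5;      // A, for the bottom plate

// energy and |dV/dr| of the 6-12 form 4 eps [(s/r)^12 - (s/r)^6] with the
// linear continuation below r_sc; returns energy, sets fr = -dV/dr / r
static inline double lj_core(double r2, double s, double eps, double r_sc,
                             double &fr) {
  if (r2 >= r_sc * r_sc) {
    double sr2 = (s * s) / r2;
    double sr6 = sr2 * sr2 * sr2;
    fr = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
    return 4.0 * eps * (sr6 * sr6 - sr6);
  }
  double r = std::sqrt(r2);
  double sc2 = (s * s) / (r_sc * r_sc);
  double sc6 = sc2 * sc2 * sc2;
  double Ec = 4.0 * eps * (sc6 * sc6 - sc6);
  double Fc = 24.0 * eps * (2.0 * sc6 * sc6 - sc6) / r_sc;  // -dV/dr at r_sc
  fr = (r > 1e-12) ? Fc / r : 0.0;
  return Ec + Fc * (r_sc - r);
}

// Core force/energy evaluation. x: 3*ne coords of emerged beads.
// bond_eq: equilibrium length per bond (ne-1). released: residues whose
// contacts are eligible. Returns total energy; fills f (3*ne), per-term
// energies (size 7), and per-contact formed flags.
static double forces(const Model &M, const std::vector<double> &x, int ne,
                     const std::vector<double> &bond_eq, int nreleased,
                     const TermFlags &fl, std::vector<double> &f,
                     double Et[7], std::vector<char> *formed,
                     double *maxf2, int tether_idx = -1,
                     const double *anchor = nullptr) {
  const Params &p = M.p;
  f.assign(3 * ne, 0.0);
  for (int k = 0; k < 7; ++k) Et[k] = 0.0;
  const double d03 = p.d0 * p.d0 * p.d0;

  // growth-point restraint: the newest, still-emerging bead is held at its
  // birth position (the tRNA-PTC attachment); counts toward the bond term
  if (tether_idx >= 0 && tether_idx < ne && anchor) {
    double dx[3], r2 = 0;
    for (int d = 0; d < 3; ++d) {
      dx[d] = x[3 * tether_idx + d] - anchor[d];
      r2 += dx[d] * dx[d];
    }
    Et[0] += p.kbond * r2;
    for (int d = 0; d < 3; ++d) f[3 * tether_idx + d] -= 2.0 * p.kbond * dx[d];
  }

  if (fl.bond) {
    for (int i = 0; i + 1 < ne; ++i) {
      double dx[3], r2 = 0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = x[3 * i + d] - x[3 * (i + 1) + d];
        r2 += dx[d] * dx[d];
      }
      double r = std::sqrt(r2);
      double dev = r - bond_eq[i];
      Et[0] += p.kbond * dev * dev;
      if (r > 1e-12) {
        double fr = -2.0 * p.kbond * dev / r;
        for (int d = 0; d < 3; ++d) {
          f[3 * i + d] += fr * dx[d];
          f[3 * (i + 1) + d] -= fr * dx[d];
        }
      }
    }
  }

  if (fl.chir) {
    for (int i = 1; i + 2 < ne; ++i) {
      double g[12];
      double C = chirality(&x[3 * (i - 1)], &x[3 * i], &x[3 * (i + 1)],
                           &x[3 * (i + 2)], d03, g);
      if (C * M.cnat[i - 1] < 0) {
        Et[1] += 0.5 * p.kappa * C * C;
        double pref = p.kappa * C / d03;
        for (int q = 0; q < 4; ++q)
          for (int d = 0; d < 3; ++d)
            f[3 * (i - 1 + q) + d] -= pref * g[3 * q + d];
      }
    }
  }

  if (fl.contacts && formed) formed->assign(M.ci.size(), 0);
  if (fl.contacts) {
    for (size_t c = 0; c < M.ci.size(); ++c) {
      int i = M.ci[c], j = M.cj[c];
      if (i >= nreleased || j >= nreleased) continue;
      double dx[3], r2 = 0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = x[3 * i + d] - x[3 * j + d];
        r2 += dx[d] * dx[d];
      }
      double r = std::sqrt(r2);
      if (r < 1e-9) stop("overlapping beads in contact pair");
      double fr;
      Et[2] += lj_core(r2, M.sij[c], p.eps, SC_CONTACT * M.sij[c], fr);
      for (int d = 0; d < 3; ++d) {
        f[3 * i + d] += fr * dx[d];
        f[3 * j + d] -= fr * dx[d];
      }
      if (formed && r < p.fold_mult * M.sij[c]) (*formed)[c] = 1;
    }
  }

  const double cut2 = p.repcut * p.repcut;
  const double s02 = p.sigma0 * p.sigma0;
  if (fl.nonnat) {
    for (int i = 0; i + 2 < ne; ++i)
      for (int j = i + 2; j < ne; ++j) {
        if (M.is_contact[(size_t)i * M.n + j]) continue;
        double dx[3], r2 = 0;
        for (int d = 0; d < 3; ++d) {
          dx[d] = x[3 * i + d] - x[3 * j + d];
          r2 += dx[d] * dx[d];
        }
        if (r2 >= cut2) continue;
        if (r2 < 1e-18) stop("overlapping beads");
        double fr;
        Et[3] += lj_core(r2, p.sigma0, p.eps, SC_WCA, fr) + p.eps;
        for (int d = 0; d < 3; ++d) {
          f[3 * i + d] += fr * dx[d];
          f[3 * j + d] -= fr * dx[d];
        }
      }
  }

  if (fl.wallatoms && M.has_wall && M.nwall > 0) {
    for (int i = 0; i < ne; ++i) {
      const double *xi = &x[3 * i];
      int c0[3], c1[3];
      bool off = false;
      for (int d = 0; d < 3; ++d) {
        if (xi[d] < M.wlo[d] - p.repcut || xi[d] > M.whi[d] + p.repcut) {
          off = true;
          break;
        }
        int c = (int)((xi[d] - M.wlo[d]) / M.cell_side);
        c0[d] = std::max(0, c - 1);
        c1[d] = std::min(M.ncell[d] - 1, c + 1);
      }
      if (off) continue;
      for (int cz = c0[2]; cz <= c1[2]; ++cz)
        for (int cy = c0[1]; cy <= c1[1]; ++cy)
          for (int cx = c0[0]; cx <= c1[0]; ++cx) {
            int a = M.chead[cx + M.ncell[0] * (cy + M.ncell[1] * cz)];
            while (a >= 0) {
              double dx[3], r2 = 0;
              for (int d = 0; d < 3; ++d) {
                dx[d] = xi[d] - M.wall[3 * a + d];
                r2 += dx[d] * dx[d];
              }
              if (r2 < cut2 && r2 > 1e-18) {
                double fr;
                Et[4] += lj_core(r2, p.sigma0, p.eps, SC_WCA, fr) + p.eps;
                for (int d = 0; d < 3; ++d) f[3 * i + d] += fr * dx[d];
              }
              a = M.cnext[a];
            }
          }
    }
  }

  if (fl.plate && M.has_plate) {
    for (int i = 0; i < ne; ++i) {
      double z = x[3 * i + 2];
      if (z <= 1e-9) stop("bead penetrated the bottom plate (z <= 0)");
      if (z >= SC_PLATE) {
        double sz = std::pow(p.sigma0 / z, p.wall_exp);
        Et[5] += p.wall_amp * p.eps * sz;
        f[3 * i + 2] += p.wall_exp * p.wall_amp * p.eps * sz / z;
      } else {
        double szc = std::pow(p.sigma0 / SC_PLATE, p.wall_exp);
        double Fc = p.wall_exp * p.wall_amp * p.eps * szc / SC_PLATE;
        Et[5] += p.wall_amp * p.eps * szc + Fc * (SC_PLATE - z);
        f[3 * i + 2] += Fc;
      }
    }
  }

  if (fl.mouth && M.has_mouth) {
    const double sm = 5.0 * std::pow(2.0, -1.0 / 6.0);
    for (int i = 0; i < ne; ++i) {
      if (M.charge[i] == 0) continue;
      for (size_t m = 0; m < M.mouth_q.size(); ++m) {
        if ((int)M.charge[i] * (int)M.mouth_q[m] >= 0) continue;
        double dx[3], r2 = 0;
        for (int d = 0; d < 3; ++d) {
          dx[d] = x[3 * i + d] - M.mouth[3 * m + d];
          r2 += dx[d] * dx[d];
        }
        if (r2 < 1e-18) stop("bead on mouth residue");
        double fr;
        Et[6] += lj_core(r2, sm, p.eps, SC_CONTACT * sm, fr);
        for (int d = 0; d < 3; ++d) f[3 * i + d] += fr * dx[d];
      }
    }
  }

  double E = 0;
  for (int k = 0; k < 7; ++k) E += Et[k];
  if (maxf2) {
    double mf = 0;
    for (int k = 0; k < 3 * ne; ++k) mf = std::max(mf, f[k] * f[k]);
    *maxf2 = mf;
  }
  return E;
}

static Params parse_params(List pl) {
  Params p;
  p.eps = as<double>(pl["epsilon"]);
  p.T = as<double>(pl["temperature"]);
  p.dt = as<double>(pl["dt"]);
  p.gamma = as<double>(pl["gamma"]);
  p.d0 = as<double>(pl["d0"]);
  p.kbond = as<double>(pl["k_bond"]);
  p.kappa = as<double>(pl["kappa"]);
  p.sigma0 = as<double>(pl["sigma0"]);
  p.repcut = as<double>(pl["rep_cutoff"]);
  p.wall_amp = as<double>(pl["wall_amp"]);
  p.wall_exp = as<double>(pl["wall_exp"]);
  p.fold_mult = as<double>(pl["fold_mult"]);
  return p;
}

static Model parse_model(List native, List pl, Nullable<List> wall_) {
  Model M;
  M.p = parse_params(pl);
  NumericMatrix nat = native["xyz"];
  M.n = nat.nrow();
  M.nat.resize(3 * M.n);
  for (int i = 0; i < M.n; ++i)
    for (int d = 0; d < 3; ++d) M.nat[3 * i + d] = nat(i, d);
  IntegerVector ch = native["charge"];
  M.charge.resize(M.n);
  for (int i = 0; i < M.n; ++i) M.charge[i] = (signed char)ch[i];
  DataFrame con = as<DataFrame>(native["contacts"]);
  IntegerVector ci = con["i"], cj = con["j"];
  NumericVector rn = con["r_nat"];
  M.is_contact.assign((size_t)M.n * M.n, 0);
  const double c6 = std::pow(2.0, -1.0 / 6.0);
  for (int c = 0; c < ci.size(); ++c) {
    int i = ci[c] - 1, j = cj[c] - 1;
    M.ci.push_back(i);
    M.cj.push_back(j);
    M.sij.push_back(rn[c] * c6);
    M.is_contact[(size_t)i * M.n + j] = 1;
    M.is_contact[(size_t)j * M.n + i] = 1;
  }
  // native chirality per quadruple (i-1, i, i+1, i+2), i = 1..n-3
  double d03 = M.p.d0 * M.p.d0 * M.p.d0;
  for (int i = 1; i + 2 < M.n; ++i)
    M.cnat.push_back(chirality(&M.nat[3 * (i - 1)], &M.nat[3 * i],
                               &M.nat[3 * (i + 1)], &M.nat[3 * (i + 2)],
                               d03, nullptr));
  if (wall_.isNotNull()) {
    List wall(wall_);
    NumericMatrix w = wall["coords"];
    M.nwall = w.nrow();
    M.has_wall = M.nwall > 0;
    M.wall.resize(3 * M.nwall);
    for (int a = 0; a < M.nwall; ++a)
      for (int d = 0; d < 3; ++d) M.wall[3 * a + d] = w(a, d);
    M.has_plate = as<bool>(wall["plate"]);
    M.mouth_z = as<double>(wall["mouth_z"]);
    if (wall.containsElementNamed("mouth_xyz") &&
        !Rf_isNull(wall["mouth_xyz"])) {
      NumericMatrix mm = wall["mouth_xyz"];
      IntegerVector mq = wall["mouth_charge"];
      M.mouth.resize(3 * mm.nrow());
      M.mouth_q.resize(mm.nrow());
      for (int a = 0; a < mm.nrow(); ++a) {
        for (int d = 0; d < 3; ++d) M.mouth[3 * a + d] = mm(a, d);
        M.mouth_q[a] = (signed char)mq[a];
      }
      M.has_mouth = true;
    }
    build_wall_cells(M);
  } else {
    M.has_plate = false;
  }
  return M;
}

static TermFlags parse_flags(Nullable<CharacterVector> terms) {
  TermFlags fl;
  if (terms.isNotNull()) {
    CharacterVector tv(terms);
    fl.bond = fl.chir = fl.contacts = fl.nonnat = fl.wallatoms = fl.plate =
        fl.mouth = false;
    for (int k = 0; k < tv.size(); ++k) {
      std::string s = as<std::string>(tv[k]);
      if (s == "bond") fl.bond = true;
      else if (s == "chirality") fl.chir = true;
      else if (s == "contacts") fl.contacts = true;
      else if (s == "nonnative") fl.nonnat = true;
      else if (s == "wall_atoms") fl.wallatoms = true;
      else if (s == "plate") fl.plate = true;
      else if (s == "mouth") fl.mouth = true;
      else stop("unknown energy term: " + s);
    }
  } else {
    fl.mouth = false;
  }
  return fl;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix x, List native, List params,
                       Nullable<List> wall, Nullable<CharacterVector> terms,
                       Nullable<NumericVector> bond_eq_,
                       int n_released = -1) {
  Model M = parse_model(native, params, wall);
  int ne = x.nrow();
  if (n_released < 0) n_released = ne;
  std::vector<double> xv(3 * ne);
  for (int i = 0; i < ne; ++i)
    for (int d = 0; d < 3; ++d) xv[3 * i + d] = x(i, d);
  std::vector<double> beq(std::max(0, ne - 1), M.p.d0);
  if (bond_eq_.isNotNull()) {
    NumericVector be(bond_eq_);
    for (int i = 0; i < be.size() && i < (int)beq.size(); ++i) beq[i] = be[i];
  }
  TermFlags fl = parse_flags(terms);
  std::vector<double> f;
  double Et[7];
  std::vector<char> formed;
  double E = forces(M, xv, ne, beq, n_released, fl, f, Et, &formed, nullptr);
  NumericMatrix fm(ne, 3);
  for (int i = 0; i < ne; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  LogicalVector fo(formed.size());
  for (size_t c = 0; c < formed.size(); ++c) fo[c] = formed[c] != 0;
  return List::create(
      _["energy"] = E,
      _["terms"] = NumericVector::create(
          _["bond"] = Et[0], _["chirality"] = Et[1], _["contacts"] = Et[2],
          _["nonnative"] = Et[3], _["wall_atoms"] = Et[4], _["plate"] = Et[5],
          _["mouth"] = Et[6]),
      _["forces"] = fm, _["formed"] = fo);
}

// Full trajectory driver. schedule: list(birth, release, t_w) per residue
// (times in tau). x0: optional pre-built chain (all residues released at
// t = 0; growth disabled).
// [[Rcpp::export]]
List cpp_run_trajectory(List native, List params, Nullable<List> wall,
                        List schedule, double t_E, int stride, int seed,
                        Nullable<NumericMatrix> x0,
                        Nullable<NumericMatrix> v0, bool use_mouth = false,
                        double z_emerge = 5.0, double emerge_jitter = 0.05,
                        int check_every = 50, bool stop_when_folded = false,
                        bool stop_when_escaped = false) {
  Model M = parse_model(native, params, wall);
  const Params &p = M.p;
  const int n = M.n;
  TermFlags fl;
  fl.mouth = use_mouth;
  fl.plate = M.has_plate;

  std::vector<double> birth(n, -1.0), release(n, 0.0), tw(n, 0.0);
  bool growing = x0.isNull();
  if (growing) {
    NumericVector b = schedule["birth"], r = schedule["release"],
                  w = schedule["t_w"];
    if (b.size() != n) stop("schedule does not cover the chain");
    for (int i = 0; i < n; ++i) {
      birth[i] = b[i];
      release[i] = r[i];
      tw[i] = w[i];
    }
  }

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 12345ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> x, v;
  int ne = 0, nreleased = 0;
  if (!growing) {
    NumericMatrix X(x0);
    ne = X.nrow();
    if (ne != n) stop("x0 must have one row per residue");
    x.resize(3 * ne);
    v.assign(3 * ne, 0.0);
    for (int i = 0; i < ne; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] = X(i, d);
    if (v0.isNotNull()) {
      NumericMatrix V(v0);
      for (int i = 0; i < ne; ++i)
        for (int d = 0; d < 3; ++d) v[3 * i + d] = V(i, d);
    }
    nreleased = n;
  } else {
    x.reserve(3 * n);
    v.reserve(3 * n);
  }

  const long long nsteps = (long long)std::llround(t_E / p.dt);
  const double c1 = std::exp(-p.gamma * p.dt);
  const double cn = std::sqrt(p.T * (1.0 - c1 * c1));

  std::vector<double> f;
  double Et[7];
  std::vector<char> formed;

  // outputs
  std::vector<double> fr_t, fr_ke, fr_pe;
  std::vector<int> fr_ne;
  std::vector<NumericMatrix> fr_x;
  std::vector<std::string> ev_name;
  std::vector<double> ev_t;
  std::vector<int> ev_res;
  double folding_time = NA_REAL, escape_time = NA_REAL;

  double anchor[3] = {0, 0, z_emerge};
  auto emerge = [&](int k, double tnow) {
    // place bead k (0-based) near the PTC with seeded lateral jitter,
    // retrying (with growing jitter) while the site clashes with a wall
    // atom or a non-bonded bead
    double jit = emerge_jitter;
    const double clash2 = 9.0;  // 3 A
    for (int attempt = 0; attempt < 100; ++attempt) {
      double px = jit * gauss(rng), py = jit * gauss(rng), pz = z_emerge;
      bool clash = false;
      if (M.has_wall) {
        for (int a = 0; a < M.nwall && !clash; ++a) {
          double dx = px - M.wall[3 * a], dy = py - M.wall[3 * a + 1],
                 dz = pz - M.wall[3 * a + 2];
          if (dx * dx + dy * dy + dz * dz < clash2) clash = true;
        }
      }
      for (int i = 0; i < ne - 1 && !clash; ++i) {  // previous bead exempt
        double dx = px - x[3 * i], dy = py - x[3 * i + 1],
               dz = pz - x[3 * i + 2];
        if (dx * dx + dy * dy + dz * dz < clash2) clash = true;
      }
      if (!clash) {
        x.push_back(px); x.push_back(py); x.push_back(pz);
        v.push_back(0.0); v.push_back(0.0); v.push_back(0.0);
        anchor[0] = px; anchor[1] = py; anchor[2] = pz;
        ++ne;
        ev_name.push_back("birth");
        ev_t.push_back(birth[k]);
        ev_res.push_back(k + 1);
        return;
      }
      jit = std::min(jit * 1.4 + 0.05, 2.0);
    }
    stop("could not place residue %d at the PTC (site blocked)", k + 1);
    (void)tnow;
  };

  std::vector<double> beq;
  auto update_beq = [&](double tnow) {
    beq.assign(std::max(0, ne - 1), p.d0);
    if (growing) {
      for (int k = 1; k < ne; ++k) {
        if (tnow < release[k]) {
          double fr = (tnow - birth[k]) / tw[k];
          if (fr < 0) fr = 0;
          if (fr > 1) fr = 1;
          beq[k - 1] = fr * p.d0;
        }
      }
    }
  };

  auto record = [&](double tnow, double pe) {
    fr_t.push_back(tnow);
    fr_ne.push_back(ne);
    double ke = 0;
    for (int k = 0; k < 3 * ne; ++k) ke += 0.5 * v[k] * v[k];
    fr_ke.push_back(ke);
    fr_pe.push_back(pe);
    NumericMatrix fx(ne, 3);
    for (int i = 0; i < ne; ++i)
      for (int d = 0; d < 3; ++d) fx(i, d) = x[3 * i + d];
    fr_x.push_back(fx);
  };

  double tnow = 0.0;
  if (growing && birth[0] <= 0.0) emerge(0, 0.0);
  update_beq(0.0);
  double maxf2 = 0;
  double pe = ne > 0
                  ? forces(M, x, ne, beq, nreleased, fl, f, Et, &formed, &maxf2, (growing && nreleased < ne) ? ne - 1 : -1, anchor)
                  : 0.0;
  record(0.0, pe);

  bool done = false;
  for (long long step = 1; step <= nsteps && !done; ++step) {
    tnow = step * p.dt;
    // births/releases whose epoch has been reached by the start of this step
    if (growing) {
      while (ne < n && birth[ne] <= (step - 1) * p.dt + 1e-9) {
        emerge(ne, tnow);
        update_beq((step - 1) * p.dt);
        pe = forces(M, x, ne, beq, nreleased, fl, f, Et, &formed, &maxf2, (growing && nreleased < ne) ? ne - 1 : -1, anchor);
      }
      while (nreleased < ne && release[nreleased] <= (step - 1) * p.dt + 1e-9) {
        ev_name.push_back("release");
        ev_t.push_back(release[nreleased]);
        ev_res.push_back(nreleased + 1);
        ++nreleased;
      }
    }
    if (ne == 0) continue;
    update_beq(tnow);

    // BAOAB
    for (int k = 0; k < 3 * ne; ++k) v[k] += 0.5 * p.dt * f[k];
    for (int k = 0; k < 3 * ne; ++k) x[k] += 0.5 * p.dt * v[k];
    if (cn > 0 || c1 != 1.0)
      for (int k = 0; k < 3 * ne; ++k) v[k] = c1 * v[k] + cn * gauss(rng);
    for (int k = 0; k < 3 * ne; ++k) x[k] += 0.5 * p.dt * v[k];
    pe = forces(M, x, ne, beq, nreleased, fl, f, Et, &formed, &maxf2, (growing && nreleased < ne) ? ne - 1 : -1, anchor);
    for (int k = 0; k < 3 * ne; ++k) v[k] += 0.5 * p.dt * f[k];

    if (maxf2 > 1e12)
      stop("numerical instability at t = %.3f tau (|force| > 1e6 eps/A)",
           tnow);

    if (step % check_every == 0) {
      if (ISNA(folding_time) && nreleased == n && !M.ci.empty()) {
        bool all = true;
        for (size_t c = 0; c < formed.size(); ++c)
          if (!formed[c]) { all = false; break; }
        if (all) {
          folding_time = tnow;
          ev_name.push_back("folded");
          ev_t.push_back(tnow);
          ev_res.push_back(NA_INTEGER);
          if (stop_when_folded) done = true;
        }
      }
      if (ISNA(escape_time) && M.has_wall && R_finite(M.mouth_z) &&
          nreleased == n) {
        bool all = ne > 0;
        for (int i = 0; i < ne; ++i)
          if (x[3 * i + 2] <= M.mouth_z) { all = false; break; }
        if (all) {
          escape_time = tnow;
          ev_name.push_back("escape");
          ev_t.push_back(tnow);
          ev_res.push_back(NA_INTEGER);
          if (stop_when_escaped) done = true;
        }
      }
    }
    if (step % stride == 0 || done || step == nsteps) record(tnow, pe);
  }

  // releases that fall exactly on the trajectory end
  while (growing && nreleased < ne && release[nreleased] <= tnow + 1e-9) {
    ev_name.push_back("release");
    ev_t.push_back(release[nreleased]);
    ev_res.push_back(nreleased + 1);
    ++nreleased;
  }

  LogicalVector fo(formed.size());
  for (size_t c = 0; c < formed.size(); ++c) fo[c] = formed[c] != 0;
  return List::create(
      _["times"] = wrap(fr_t), _["n_emerged"] = wrap(fr_ne),
      _["kinetic"] = wrap(fr_ke), _["potential"] = wrap(fr_pe),
      _["frames"] = wrap(fr_x),
      _["events"] = DataFrame::create(_["event"] = wrap(ev_name),
                                      _["time"] = wrap(ev_t),
                                      _["residue"] = wrap(ev_res),
                                      _["stringsAsFactors"] = false),
      _["folding_time"] = folding_time, _["escape_time"] = escape_time,
      _["formed"] = fo, _["t_end"] = tnow, _["n_final"] = ne);
}
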