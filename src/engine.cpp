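// Desk-scale coarse-grained MD core.
//
// Velocity-Verlet / BAOAB integration with optional Langevin (exact
// Ornstein-Uhlenbeck midpoint step, restrictable to axes and to a bead
// group) or Nose-Hoover thermostatting, SHAKE/RATTLE distance constraints,
// force-switched 12-6 LJ, damped force-shifted Coulomb, harmonic bonds and
// angles, a Verlet neighbour list, a frozen lower anchor sheet and a rigid
// upper anchor sheet driven at constant sliding velocity under a constant
// normal load.  Units: nm, ps, amu, kJ/mol, e (1 kJ/mol = 1 amu nm^2/ps^2).
//
// The RNG is a self-contained splitmix64/Box-Muller pair so that identical
// (state, config, seed) inputs give bit-identical trajectories.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

struct Rng {
  uint64_t s;
  bool have_cache = false;
  double cache = 0.0;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.0e-17;
  }
  double norm() {
    if (have_cache) { have_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cache = r * std::sin(2.0 * M_PI * u2);
    have_cache = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct SwitchCoefs { double A12, B12, C12, A6, B6, C6; };

static SwitchCoefs fswitch(double r1, double rc) {
  SwitchCoefs c;
  auto mk = [&](double p, double &A, double &B, double &C) {
    A = -p * ((p + 4) * rc - (p + 1) * r1) /
        (std::pow(rc, p + 2) * (rc - r1) * (rc - r1));
    B = p * ((p + 3) * rc - (p + 1) * r1) /
        (std::pow(rc, p + 2) * std::pow(rc - r1, 3));
    C = std::pow(rc, -p) - (A / 3) * std::pow(rc - r1, 3) -
        (B / 4) * std::pow(rc - r1, 4);
  };
  mk(12, c.A12, c.B12, c.C12);
  mk(6, c.A6, c.B6, c.C6);
  return c;
}

struct Engine {
  int n;
  std::vector<double> x, v, f, mass, charge;
  std::vector<int> ljidx, group; // group: 0 mobile, 1 lower, 2 upper
  std::vector<char> thermo;      // thermostat group mask
  int ntypes;
  std::vector<double> epsM, sigM; // ntypes x ntypes
  // bonded terms
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_K;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_K;
  std::vector<int> c_i, c_j; std::vector<double> c_d;
  // exclusions: per-atom sorted lists
  std::vector<std::vector<int>> excl;
  double box[3]; bool per[3];
  // options
  bool lj_on, lj_switch, coul_on;
  double lj_ron, lj_rcut, coul_f, coul_alpha, coul_rcut;
  SwitchCoefs sw;
  double wall_k, wall_zlo, wall_zhi; bool wall_on;
  // neighbour list
  double skin, rlist2;
  std::vector<int> nl_i, nl_j;
  std::vector<double> x_at_build;
  // upper anchor rigid body
  bool has_upper = false;
  double upM = 0.0, upVz = 0.0, load_force = 0.0, vs = 0.0;
  // diagnostics
  double pe = 0.0;
  double fz_lower = 0.0, fx_upper = 0.0, fz_upper = 0.0;

  double mind(double d, int ax) const {
    if (per[ax]) d -= box[ax] * std::nearbyint(d / box[ax]);
    return d;
  }

  void build_list() {
    nl_i.clear(); nl_j.clear();
    double rl = std::sqrt(rlist2);
    // cell list over periodic/non-periodic box extents
    double lo[3], hi[3]; int nc[3];
    for (int ax = 0; ax < 3; ax++) {
      if (per[ax]) { lo[ax] = 0; hi[ax] = box[ax]; }
      else {
        lo[ax] = hi[ax] = x[ax];
        for (int i = 1; i < n; i++) {
          lo[ax] = std::min(lo[ax], x[3 * i + ax]);
          hi[ax] = std::max(hi[ax], x[3 * i + ax]);
        }
        lo[ax] -= 1e-9; hi[ax] += 1e-9;
      }
      nc[ax] = std::max(1, (int)std::floor((hi[ax] - lo[ax]) / rl));
      if (per[ax] && nc[ax] < 3) nc[ax] = 1; // fall back to brute per axis
    }
    long ncell = (long)nc[0] * nc[1] * nc[2];
    if (ncell <= 8 || n < 64) {
      // brute force
      for (int i = 0; i < n - 1; i++)
        for (int j = i + 1; j < n; j++) add_pair_if(i, j);
    } else {
      std::vector<std::vector<int>> cells(ncell);
      auto cidx = [&](int i, int out[3]) {
        for (int ax = 0; ax < 3; ax++) {
          double xx = x[3 * i + ax];
          if (per[ax]) xx -= box[ax] * std::floor(xx / box[ax]);
          int c = (int)((xx - lo[ax]) / (hi[ax] - lo[ax]) * nc[ax]);
          out[ax] = std::min(std::max(c, 0), nc[ax] - 1);
        }
      };
      for (int i = 0; i < n; i++) {
        int c[3]; cidx(i, c);
        cells[(c[0] * nc[1] + c[1]) * (long)nc[2] + c[2]].push_back(i);
      }
      // per-axis neighbour offsets, deduplicated for small periodic counts
      std::vector<int> offs[3];
      for (int ax = 0; ax < 3; ax++) {
        if (per[ax] && nc[ax] == 1) offs[ax] = {0};
        else if (per[ax] && nc[ax] == 2) offs[ax] = {0, 1};
        else offs[ax] = {-1, 0, 1};
      }
      for (int cx = 0; cx < nc[0]; cx++)
        for (int cy = 0; cy < nc[1]; cy++)
          for (int cz = 0; cz < nc[2]; cz++) {
            long c0 = (cx * (long)nc[1] + cy) * nc[2] + cz;
            const std::vector<int> &A = cells[c0];
            if (A.empty()) continue;
            for (int dx : offs[0])
              for (int dy : offs[1])
                for (int dz : offs[2]) {
                  int ex = cx + dx, ey = cy + dy, ez = cz + dz;
                  if (per[0]) ex = (ex + nc[0]) % nc[0];
                  else if (ex < 0 || ex >= nc[0]) continue;
                  if (per[1]) ey = (ey + nc[1]) % nc[1];
                  else if (ey < 0 || ey >= nc[1]) continue;
                  if (per[2]) ez = (ez + nc[2]) % nc[2];
                  else if (ez < 0 || ez >= nc[2]) continue;
                  long c1 = (ex * (long)nc[1] + ey) * nc[2] + ez;
                  if (c1 < c0) continue;
                  const std::vector<int> &B = cells[c1];
                  if (c1 == c0) {
                    for (size_t a = 0; a < A.size(); a++)
                      for (size_t b = a + 1; b < A.size(); b++)
                        add_pair_if(std::min(A[a], A[b]),
                                    std::max(A[a], A[b]));
                  } else {
                    for (int ia : A) for (int ib : B)
                      add_pair_if(std::min(ia, ib), std::max(ia, ib));
                  }
                }
          }
    }
    x_at_build = x;
  }

  void add_pair_if(int i, int j) {
    // both in the same frozen/rigid anchor: skip
    if (group[i] != 0 && group[i] == group[j]) return;
    const std::vector<int> &e = excl[i];
    if (std::binary_search(e.begin(), e.end(), j)) return;
    double d2 = 0;
    for (int ax = 0; ax < 3; ax++) {
      double d = mind(x[3 * i + ax] - x[3 * j + ax], ax);
      d2 += d * d;
    }
    if (d2 < rlist2) { nl_i.push_back(i); nl_j.push_back(j); }
  }

  bool need_rebuild() const {
    double half = skin * 0.5, m1 = 0, m2 = 0;
    for (int i = 0; i < n; i++) {
      double d2 = 0;
      for (int ax = 0; ax < 3; ax++) {
        double d = x[3 * i + ax] - x_at_build[3 * i + ax];
        d2 += d * d;
      }
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) m2 = d2;
    }
    return std::sqrt(m1) + std::sqrt(m2) > 2 * half;
  }

  void forces() {
    std::fill(f.begin(), f.end(), 0.0);
    pe = 0.0;
    // bonds
    for (size_t b = 0; b < b_i.size(); b++) {
      int i = b_i[b], j = b_j[b];
      double d[3], r2 = 0;
      for (int ax = 0; ax < 3; ax++) {
        d[ax] = mind(x[3 * i + ax] - x[3 * j + ax], ax);
        r2 += d[ax] * d[ax];
      }
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("bond between beads %d and %d has zero length",
                          i + 1, j + 1);
      double dr = r - b_r0[b];
      pe += b_K[b] * dr * dr;
      double fr = -2.0 * b_K[b] * dr / r; // along d, on i
      for (int ax = 0; ax < 3; ax++) {
        f[3 * i + ax] += fr * d[ax];
        f[3 * j + ax] -= fr * d[ax];
      }
    }
    // angles (apex j)
    for (size_t t = 0; t < a_i.size(); t++) {
      int i = a_i[t], j = a_j[t], k = a_k[t];
      double a[3], b[3], na2 = 0, nb2 = 0, ab = 0;
      for (int ax = 0; ax < 3; ax++) {
        a[ax] = mind(x[3 * i + ax] - x[3 * j + ax], ax);
        b[ax] = mind(x[3 * k + ax] - x[3 * j + ax], ax);
        na2 += a[ax] * a[ax]; nb2 += b[ax] * b[ax]; ab += a[ax] * b[ax];
      }
      double na = std::sqrt(na2), nb = std::sqrt(nb2);
      if (na < 1e-10 || nb < 1e-10) continue; // degenerate; skip
      double ct = ab / (na * nb);
      ct = std::min(1.0, std::max(-1.0, ct));
      double th = std::acos(ct);
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-14));
      double dth = th - a_t0[t];
      pe += a_K[t] * dth * dth;
      double coef = 2.0 * a_K[t] * dth / st; // F_i = (dE/dtheta / sin) d(cos)/da
      for (int ax = 0; ax < 3; ax++) {
        double fi = coef * (b[ax] / (na * nb) - ct * a[ax] / na2);
        double fk = coef * (a[ax] / (na * nb) - ct * b[ax] / nb2);
        f[3 * i + ax] += fi;
        f[3 * k + ax] += fk;
        f[3 * j + ax] -= fi + fk;
      }
    }
    // nonbonded via neighbour list
    double ljc2 = lj_rcut * lj_rcut, qc2 = coul_rcut * coul_rcut;
    double erfc_c = 0, derfc_c = 0;
    if (coul_on) {
      double rc = coul_rcut, a = coul_alpha;
      if (a > 0) {
        erfc_c = std::erfc(a * rc) / rc;
        derfc_c = -(std::erfc(a * rc) / (rc * rc) +
                    2.0 * a / std::sqrt(M_PI) * std::exp(-a * a * rc * rc) / rc);
      } else {
        erfc_c = 1.0 / rc;
        derfc_c = -1.0 / (rc * rc);
      }
    }
    for (size_t p = 0; p < nl_i.size(); p++) {
      int i = nl_i[p], j = nl_j[p];
      double d[3], r2 = 0;
      for (int ax = 0; ax < 3; ax++) {
        d[ax] = mind(x[3 * i + ax] - x[3 * j + ax], ax);
        r2 += d[ax] * d[ax];
      }
      double fr = 0.0; // (1/r dE/dr) accumulated as f = -dE/dr / r
      if (lj_on && r2 < ljc2) {
        double eps = epsM[ljidx[i] * ntypes + ljidx[j]];
        if (eps > 0) {
          double sig = sigM[ljidx[i] * ntypes + ljidx[j]];
          double s2 = sig * sig, s6 = s2 * s2 * s2, s12 = s6 * s6;
          double ir2 = 1.0 / r2, ir = std::sqrt(ir2);
          double r = r2 * ir;
          double V12, V6, F12, F6;
          double ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
          if (!lj_switch) {
            V12 = ir12; V6 = ir6;
            F12 = 12.0 * ir12 * ir; F6 = 6.0 * ir6 * ir;
          } else if (r <= lj_ron) {
            V12 = ir12 - sw.C12; V6 = ir6 - sw.C6;
            F12 = 12.0 * ir12 * ir; F6 = 6.0 * ir6 * ir;
          } else {
            double dr1 = r - lj_ron;
            V12 = ir12 - (sw.A12 / 3) * dr1 * dr1 * dr1 -
                  (sw.B12 / 4) * dr1 * dr1 * dr1 * dr1 - sw.C12;
            V6 = ir6 - (sw.A6 / 3) * dr1 * dr1 * dr1 -
                 (sw.B6 / 4) * dr1 * dr1 * dr1 * dr1 - sw.C6;
            F12 = 12.0 * ir12 * ir + sw.A12 * dr1 * dr1 +
                  sw.B12 * dr1 * dr1 * dr1;
            F6 = 6.0 * ir6 * ir + sw.A6 * dr1 * dr1 + sw.B6 * dr1 * dr1 * dr1;
          }
          pe += 4.0 * eps * (s12 * V12 - s6 * V6);
          fr += 4.0 * eps * (s12 * F12 - s6 * F6) * ir; // -dE/dr * (1/r)
        }
      }
      if (coul_on && r2 < qc2) {
        double qq = charge[i] * charge[j];
        if (qq != 0.0) {
          double r = std::sqrt(r2), a = coul_alpha;
          double Er, dEr; // erfc(ar)/r and its derivative
          if (a > 0) {
            Er = std::erfc(a * r) / r;
            dEr = -(std::erfc(a * r) / (r * r) +
                    2.0 * a / std::sqrt(M_PI) * std::exp(-a * a * r * r) / r);
          } else {
            Er = 1.0 / r; dEr = -1.0 / (r * r);
          }
          // force-shifted: E(r) - E(rc) - E'(rc)(r - rc)
          pe += coul_f * qq * (Er - erfc_c - derfc_c * (r - coul_rcut));
          double force = -coul_f * qq * (dEr - derfc_c); // -dE/dr
          fr += force / r;
        }
      }
      if (fr != 0.0) {
        for (int ax = 0; ax < 3; ax++) {
          f[3 * i + ax] += fr * d[ax];
          f[3 * j + ax] -= fr * d[ax];
        }
      }
    }
    // repulsive harmonic walls (act on non-anchor beads)
    if (wall_on) {
      for (int i = 0; i < n; i++) {
        if (group[i] != 0) continue;
        double z = x[3 * i + 2];
        if (z > wall_zhi) {
          double dz = z - wall_zhi;
          pe += wall_k * dz * dz;
          f[3 * i + 2] -= 2.0 * wall_k * dz;
        }
        if (z < wall_zlo) {
          double dz = z - wall_zlo;
          pe += wall_k * dz * dz;
          f[3 * i + 2] -= 2.0 * wall_k * dz;
        }
      }
    }
    // anchor force diagnostics
    fz_lower = fx_upper = fz_upper = 0.0;
    for (int i = 0; i < n; i++) {
      if (group[i] == 1) fz_lower += f[3 * i + 2];
      else if (group[i] == 2) { fx_upper += f[3 * i]; fz_upper += f[3 * i + 2]; }
    }
    for (int i = 0; i < n; i++)
      if (!std::isfinite(f[3 * i]) || !std::isfinite(f[3 * i + 1]) ||
          !std::isfinite(f[3 * i + 2]))
        stop("non-finite force on bead %d", i + 1);
  }

  void shake(const std::vector<double> &xref, double dteff, double tol,
             int maxit) {
    if (c_i.empty()) return;
    for (int it = 0; it < maxit; it++) {
      double worst = 0;
      for (size_t c = 0; c < c_i.size(); c++) {
        int i = c_i[c], j = c_j[c];
        double d[3], r2 = 0, dr[3], rrd = 0;
        for (int ax = 0; ax < 3; ax++) {
          d[ax] = mind(x[3 * i + ax] - x[3 * j + ax], ax);
          dr[ax] = mind(xref[3 * i + ax] - xref[3 * j + ax], ax);
          r2 += d[ax] * d[ax];
          rrd += d[ax] * dr[ax];
        }
        double d2 = c_d[c] * c_d[c];
        double diff = r2 - d2;
        worst = std::max(worst, std::fabs(std::sqrt(r2) - c_d[c]));
        double im = 1.0 / mass[i] + 1.0 / mass[j];
        double g = diff / (2.0 * im * rrd);
        for (int ax = 0; ax < 3; ax++) {
          double corr = g * dr[ax];
          x[3 * i + ax] -= corr / mass[i];
          x[3 * j + ax] += corr / mass[j];
          if (dteff > 0) {
            v[3 * i + ax] -= corr / (mass[i] * dteff);
            v[3 * j + ax] += corr / (mass[j] * dteff);
          }
        }
      }
      if (worst < tol) return;
    }
    stop("SHAKE failed to converge for a constrained molecule (beads %d-%d)",
         c_i[0] + 1, c_j[0] + 1);
  }

  void rattle() {
    if (c_i.empty()) return;
    for (int it = 0; it < 50; it++) {
      double worst = 0;
      for (size_t c = 0; c < c_i.size(); c++) {
        int i = c_i[c], j = c_j[c];
        double d[3], rv = 0, r2 = 0;
        for (int ax = 0; ax < 3; ax++) {
          d[ax] = mind(x[3 * i + ax] - x[3 * j + ax], ax);
          rv += d[ax] * (v[3 * i + ax] - v[3 * j + ax]);
          r2 += d[ax] * d[ax];
        }
        double im = 1.0 / mass[i] + 1.0 / mass[j];
        double kcoef = rv / (r2 * im);
        worst = std::max(worst, std::fabs(rv));
        for (int ax = 0; ax < 3; ax++) {
          v[3 * i + ax] -= kcoef * d[ax] / mass[i];
          v[3 * j + ax] += kcoef * d[ax] / mass[j];
        }
      }
      if (worst < 1e-12) return;
    }
  }
};

// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector charge, IntegerVector ljidx, int ntypes,
                NumericVector epsM, NumericVector sigM,
                IntegerVector b_i, IntegerVector b_j, NumericVector b_r0,
                NumericVector b_K,
                IntegerVector a_i, IntegerVector a_j, IntegerVector a_k,
                NumericVector a_t0, NumericVector a_K,
                IntegerVector c_i, IntegerVector c_j, NumericVector c_d,
                IntegerVector e_i, IntegerVector e_j,
                NumericVector box, LogicalVector periodic,
                IntegerVector group, LogicalVector thermo_mask,
                List opts) {
  Engine E;
  E.n = pos.nrow();
  E.x.resize(3 * E.n); E.v.resize(3 * E.n); E.f.assign(3 * E.n, 0.0);
  E.mass.resize(E.n); E.charge.resize(E.n);
  E.ljidx.resize(E.n); E.group.resize(E.n); E.thermo.resize(E.n);
  for (int i = 0; i < E.n; i++) {
    for (int ax = 0; ax < 3; ax++) {
      E.x[3 * i + ax] = pos(i, ax);
      E.v[3 * i + ax] = vel(i, ax);
    }
    E.mass[i] = mass[i]; E.charge[i] = charge[i];
    E.ljidx[i] = ljidx[i]; E.group[i] = group[i];
    E.thermo[i] = thermo_mask[i] ? 1 : 0;
  }
  E.ntypes = ntypes;
  E.epsM.assign(epsM.begin(), epsM.end());
  E.sigM.assign(sigM.begin(), sigM.end());
  E.b_i.assign(b_i.begin(), b_i.end()); E.b_j.assign(b_j.begin(), b_j.end());
  E.b_r0.assign(b_r0.begin(), b_r0.end());
  E.b_K.assign(b_K.begin(), b_K.end());
  E.a_i.assign(a_i.begin(), a_i.end()); E.a_j.assign(a_j.begin(), a_j.end());
  E.a_k.assign(a_k.begin(), a_k.end());
  E.a_t0.assign(a_t0.begin(), a_t0.end());
  E.a_K.assign(a_K.begin(), a_K.end());
  E.c_i.assign(c_i.begin(), c_i.end()); E.c_j.assign(c_j.begin(), c_j.end());
  E.c_d.assign(c_d.begin(), c_d.end());
  E.excl.assign(E.n, {});
  for (int p = 0; p < e_i.size(); p++) {
    E.excl[e_i[p]].push_back(e_j[p]);
    E.excl[e_j[p]].push_back(e_i[p]);
  }
  for (auto &v : E.excl) std::sort(v.begin(), v.end());
  for (int ax = 0; ax < 3; ax++) {
    E.box[ax] = box[ax]; E.per[ax] = periodic[ax];
  }
  // options
  int n_steps = as<int>(opts["n_steps"]);
  double dt = as<double>(opts["dt"]);
  int sample_every = as<int>(opts["sample_every"]);
  int frame_every = as<int>(opts["frame_every"]);
  int thermostat = as<int>(opts["thermostat"]); // 0 none 1 langevin 2 NH
  double T_target = as<double>(opts["T_target"]);
  double damp = as<double>(opts["damp"]);
  LogicalVector axes = opts["axes"];
  uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  E.lj_on = as<bool>(opts["lj_on"]);
  E.lj_switch = as<bool>(opts["lj_switch"]);
  E.lj_ron = as<double>(opts["lj_r_on"]);
  E.lj_rcut = as<double>(opts["lj_r_cut"]);
  E.sw = fswitch(E.lj_ron, E.lj_rcut);
  E.coul_on = as<bool>(opts["coul_on"]);
  E.coul_f = as<double>(opts["coul_f"]);
  E.coul_alpha = as<double>(opts["coul_alpha"]);
  E.coul_rcut = as<double>(opts["coul_r_cut"]);
  E.wall_on = as<bool>(opts["wall_on"]);
  E.wall_k = as<double>(opts["wall_k"]);
  E.wall_zlo = as<double>(opts["wall_zlo"]);
  E.wall_zhi = as<double>(opts["wall_zhi"]);
  E.skin = as<double>(opts["skin"]);
  double shake_tol = as<double>(opts["shake_tol"]);
  double load_total = as<double>(opts["load_force"]); // downward, kJ/mol/nm
  E.vs = as<double>(opts["v_s"]);
  bool single_point = as<bool>(opts["single_point"]);

  double rmax = 0.0;
  if (E.lj_on) rmax = std::max(rmax, E.lj_rcut);
  if (E.coul_on) rmax = std::max(rmax, E.coul_rcut);
  if (rmax == 0.0) rmax = 0.1; // bonded-only: tiny list
  for (int ax = 0; ax < 3; ax++)
    if (E.per[ax] && rmax > E.box[ax] / 2 + 1e-9)
      stop("cutoff %g exceeds half the box edge in axis %d", rmax, ax + 1);
  E.rlist2 = (rmax + E.skin) * (rmax + E.skin);
  E.load_force = load_total;

  // upper anchor rigid body
  int n_upper = 0;
  for (int i = 0; i < E.n; i++) if (E.group[i] == 2) {
    n_upper++; E.upM += E.mass[i];
  }
  E.has_upper = n_upper > 0;
  // mobile dof
  int n_mobile = 0;
  for (int i = 0; i < E.n; i++) if (E.group[i] == 0) n_mobile++;
  int ndof = 3 * n_mobile - (int)E.c_i.size();
  if (ndof < 1) ndof = 1;

  Rng rng(seed);
  E.build_list();
  E.forces();

  if (single_point) {
    NumericMatrix fout(E.n, 3);
    for (int i = 0; i < E.n; i++)
      for (int ax = 0; ax < 3; ax++) fout(i, ax) = E.f[3 * i + ax];
    return List::create(_["pe"] = E.pe, _["forces"] = fout);
  }

  int nsamp = n_steps / sample_every;
  NumericMatrix scal(nsamp, 9);
  colnames(scal) = CharacterVector::create("step", "time", "KE", "PE", "T",
                                           "gap", "fz_lower", "fx_upper",
                                           "fz_upper");
  int nfr = frame_every > 0 ? n_steps / frame_every : 0;
  NumericVector frames(nfr > 0 ? (R_xlen_t)E.n * 3 * nfr : 0);
  NumericVector vframes(nfr > 0 ? (R_xlen_t)E.n * 3 * nfr : 0);
  NumericVector ftime(nfr > 0 ? nfr : 0);

  double nh_xi = 0.0;
  double c1 = 0.0, Tdof = 0.0;
  if (thermostat == 1) c1 = std::exp(-dt / damp);
  // thermostatted dof for NH
  if (thermostat == 2) {
    int nt = 0;
    for (int i = 0; i < E.n; i++) if (E.group[i] == 0 && E.thermo[i]) nt++;
    int nax = 0; for (int ax = 0; ax < 3; ax++) if (axes[ax]) nax++;
    Tdof = std::max(1, nt * nax - (int)E.c_i.size());
  }

  std::vector<double> xref(3 * E.n);
  int isamp = 0, ifr = 0;
  // per-step accumulators so logged anchor forces and gap are interval means
  double acc_fzl = 0, acc_fxu = 0, acc_fzu = 0, acc_gap = 0;
  int acc_n = 0;

  for (int step = 1; step <= n_steps; step++) {
    // B: half kick
    for (int i = 0; i < E.n; i++) {
      if (E.group[i] != 0) continue;
      for (int ax = 0; ax < 3; ax++)
        E.v[3 * i + ax] += 0.5 * dt * E.f[3 * i + ax] / E.mass[i];
    }
    if (E.has_upper)
      E.upVz += 0.5 * dt * (E.fz_upper - E.load_force) / E.upM;
    E.rattle();
    // A: half drift
    xref = E.x;
    for (int i = 0; i < E.n; i++) {
      if (E.group[i] == 0) {
        for (int ax = 0; ax < 3; ax++)
          E.x[3 * i + ax] += 0.5 * dt * E.v[3 * i + ax];
      } else if (E.group[i] == 2) {
        E.x[3 * i] += 0.5 * dt * E.vs;
        E.x[3 * i + 2] += 0.5 * dt * E.upVz;
      }
    }
    E.shake(xref, 0.5 * dt, shake_tol, 500);
    // O: thermostat
    if (thermostat == 1) {
      double sig1 = std::sqrt(1.0 - c1 * c1);
      for (int i = 0; i < E.n; i++) {
        if (E.group[i] != 0 || !E.thermo[i]) continue;
        double s = sig1 * std::sqrt(KB * T_target / E.mass[i]);
        for (int ax = 0; ax < 3; ax++) {
          if (!axes[ax]) continue;
          E.v[3 * i + ax] = c1 * E.v[3 * i + ax] + s * rng.norm();
        }
      }
      E.rattle();
    } else if (thermostat == 2) {
      double ke2 = 0.0;
      for (int i = 0; i < E.n; i++) {
        if (E.group[i] != 0 || !E.thermo[i]) continue;
        for (int ax = 0; ax < 3; ax++)
          if (axes[ax]) ke2 += E.mass[i] * E.v[3 * i + ax] * E.v[3 * i + ax];
      }
      double Q = Tdof * KB * T_target * damp * damp;
      nh_xi += dt * (ke2 - Tdof * KB * T_target) / Q;
      double sc = std::exp(-nh_xi * dt);
      for (int i = 0; i < E.n; i++) {
        if (E.group[i] != 0 || !E.thermo[i]) continue;
        for (int ax = 0; ax < 3; ax++)
          if (axes[ax]) E.v[3 * i + ax] *= sc;
      }
      E.rattle();
    }
    // A: half drift
    xref = E.x;
    for (int i = 0; i < E.n; i++) {
      if (E.group[i] == 0) {
        for (int ax = 0; ax < 3; ax++)
          E.x[3 * i + ax] += 0.5 * dt * E.v[3 * i + ax];
      } else if (E.group[i] == 2) {
        E.x[3 * i] += 0.5 * dt * E.vs;
        E.x[3 * i + 2] += 0.5 * dt * E.upVz;
      }
    }
    E.shake(xref, 0.5 * dt, shake_tol, 500);
    // forces at new positions
    if (E.need_rebuild()) E.build_list();
    E.forces();
    // B: half kick
    for (int i = 0; i < E.n; i++) {
      if (E.group[i] != 0) continue;
      for (int ax = 0; ax < 3; ax++)
        E.v[3 * i + ax] += 0.5 * dt * E.f[3 * i + ax] / E.mass[i];
    }
    if (E.has_upper)
      E.upVz += 0.5 * dt * (E.fz_upper - E.load_force) / E.upM;
    E.rattle();

    acc_fzl += E.fz_lower; acc_fxu += E.fx_upper; acc_fzu += E.fz_upper;
    if (E.has_upper) {
      double zl = 0, zu = 0; int nl = 0, nu = 0;
      for (int i = 0; i < E.n; i++) {
        if (E.group[i] == 1) { zl += E.x[3 * i + 2]; nl++; }
        else if (E.group[i] == 2) { zu += E.x[3 * i + 2]; nu++; }
      }
      if (nl > 0 && nu > 0) acc_gap += zu / nu - zl / nl;
    }
    acc_n++;

    if (step % sample_every == 0 && isamp < nsamp) {
      double ke = 0.0;
      for (int i = 0; i < E.n; i++) {
        if (E.group[i] != 0) continue;
        for (int ax = 0; ax < 3; ax++)
          ke += 0.5 * E.mass[i] * E.v[3 * i + ax] * E.v[3 * i + ax];
      }
      scal(isamp, 0) = step;
      scal(isamp, 1) = step * dt;
      scal(isamp, 2) = ke;
      scal(isamp, 3) = E.pe;
      scal(isamp, 4) = 2.0 * ke / (ndof * KB);
      scal(isamp, 5) = E.has_upper ? acc_gap / acc_n : NA_REAL;
      scal(isamp, 6) = acc_fzl / acc_n;
      scal(isamp, 7) = acc_fxu / acc_n;
      scal(isamp, 8) = acc_fzu / acc_n;
      acc_fzl = acc_fxu = acc_fzu = acc_gap = 0; acc_n = 0;
      isamp++;
    }
    if (frame_every > 0 && step % frame_every == 0 && ifr < nfr) {
      for (int i = 0; i < E.n; i++)
        for (int ax = 0; ax < 3; ax++) {
          frames[(R_xlen_t)ifr * 3 * E.n + ax * E.n + i] = E.x[3 * i + ax];
          vframes[(R_xlen_t)ifr * 3 * E.n + ax * E.n + i] = E.v[3 * i + ax];
        }
      ftime[ifr] = step * dt;
      ifr++;
    }
  }

  NumericMatrix xout(E.n, 3), vout(E.n, 3);
  for (int i = 0; i < E.n; i++)
    for (int ax = 0; ax < 3; ax++) {
      xout(i, ax) = E.x[3 * i + ax];
      vout(i, ax) = E.v[3 * i + ax];
    }
  List out = List::create(_["scalars"] = scal, _["pos"] = xout,
                          _["vel"] = vout, _["pe"] = E.pe);
  if (nfr > 0) {
    frames.attr("dim") = IntegerVector::create(E.n, 3, nfr);
    vframes.attr("dim") = IntegerVector::create(E.n, 3, nfr);
    out["frames"] = frames;
    out["vel_frames"] = vframes;
    out["frame_time"] = ftime;
  }
  return out;
}
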