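// Core numerical kernels: Go-model energies/forces and the BAOAB Langevin
// integrator. Distances in angstrom, energies in kcal/mol, masses in amu,
// time in ps. KFAC converts kcal/mol to amu*A^2/ps^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <random>

using namespace Rcpp;

static const double KFAC = 418.4;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vscale(const Vec3 &a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}

// System description shared by the one-shot evaluator and the integrator.
struct GoSystem {
  int n;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0;
  // angles (j is the vertex)
  std::vector<int> ai, aj, ak;
  std::vector<double> ath0;
  // dihedrals
  std::vector<int> di, dj, dk, dl;
  std::vector<double> dphi0;
  // native contacts
  std::vector<int> ni, nj;
  std::vector<double> nsig;
  // pairs excluded from the non-native repulsion (1-2, 1-3, native)
  std::unordered_set<long long> skip;
  // parameters
  double eps_n, eps_nn, sigma_rep, k_bond, k_angle, k_dihedral;
  int form; // 0 = printed 12-10 (4eps[(s/r)^12-(s/r)^10]), 1 = standard SBM
  double rcut_nn;          // non-native truncation
  double native_cut_factor; // native term truncated at factor * sigma
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

static GoSystem build_system(int n, List sys) {
  GoSystem S;
  S.n = n;
  IntegerVector bi = sys["bond_i"], bj = sys["bond_j"];
  NumericVector br0 = sys["bond_r0"];
  S.bi.assign(bi.begin(), bi.end());
  S.bj.assign(bj.begin(), bj.end());
  S.br0.assign(br0.begin(), br0.end());
  IntegerVector ai = sys["angle_i"], aj = sys["angle_j"], ak = sys["angle_k"];
  NumericVector ath0 = sys["angle_theta0"];
  S.ai.assign(ai.begin(), ai.end());
  S.aj.assign(aj.begin(), aj.end());
  S.ak.assign(ak.begin(), ak.end());
  S.ath0.assign(ath0.begin(), ath0.end());
  IntegerVector di = sys["dih_i"], dj = sys["dih_j"], dk = sys["dih_k"],
                dl = sys["dih_l"];
  NumericVector dphi0 = sys["dih_phi0"];
  S.di.assign(di.begin(), di.end());
  S.dj.assign(dj.begin(), dj.end());
  S.dk.assign(dk.begin(), dk.end());
  S.dl.assign(dl.begin(), dl.end());
  S.dphi0.assign(dphi0.begin(), dphi0.end());
  IntegerVector ni = sys["nat_i"], nj = sys["nat_j"];
  NumericVector nsig = sys["nat_sigma"];
  S.ni.assign(ni.begin(), ni.end());
  S.nj.assign(nj.begin(), nj.end());
  S.nsig.assign(nsig.begin(), nsig.end());
  IntegerVector si = sys["skip_i"], sj = sys["skip_j"];
  S.skip.reserve(si.size() * 2);
  for (int k = 0; k < si.size(); ++k)
    S.skip.insert(pkey(si[k], sj[k], n));
  // 1-2 and 1-3 pairs arrive through skip_i/skip_j together with natives.
  S.eps_n = as<double>(sys["eps_native"]);
  S.eps_nn = as<double>(sys["eps_nonnative"]);
  S.sigma_rep = as<double>(sys["sigma_rep"]);
  S.k_bond = as<double>(sys["k_bond"]);
  S.k_angle = as<double>(sys["k_angle"]);
  S.k_dihedral = as<double>(sys["k_dihedral"]);
  S.form = as<int>(sys["form"]);
  S.rcut_nn = 3.0 * S.sigma_rep;
  S.native_cut_factor = 3.0;
  return S;
}

struct EnergyAcc {
  double native = 0.0, nonnative = 0.0, bond = 0.0, angle = 0.0, dih = 0.0;
  double total() const { return native + nonnative + bond + angle + dih; }
};

// Candidate pair list for the repulsive term (Verlet list).
struct PairList {
  std::vector<int> pi, pj;
  std::vector<double> ref; // positions at last build
  double skin = 2.0;
  bool valid = false;

  void build(const std::vector<double> &pos, const GoSystem &S) {
    pi.clear();
    pj.clear();
    const double rl = S.rcut_nn + skin;
    const double rl2 = rl * rl;
    for (int i = 0; i < S.n; ++i) {
      for (int j = i + 1; j < S.n; ++j) {
        double dx = pos[3 * i] - pos[3 * j];
        double dy = pos[3 * i + 1] - pos[3 * j + 1];
        double dz = pos[3 * i + 2] - pos[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > rl2) continue;
        if (S.skip.count(pkey(i, j, S.n))) continue;
        pi.push_back(i);
        pj.push_back(j);
      }
    }
    ref = pos;
    valid = true;
  }

  bool stale(const std::vector<double> &pos) const {
    if (!valid) return true;
    const double lim2 = 0.25 * skin * skin; // (skin/2)^2
    for (size_t i = 0; i < pos.size(); i += 3) {
      double dx = pos[i] - ref[i];
      double dy = pos[i + 1] - ref[i + 1];
      double dz = pos[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// Accumulate energy and (optionally) forces. Returns false on a
// non-native near-singularity (overlapping atoms).
static bool eval_forces(const std::vector<double> &pos, const GoSystem &S,
                        PairList &plist, EnergyAcc &E,
                        std::vector<double> *F, int *bad_pair) {
  E = EnergyAcc();
  if (F) std::fill(F->begin(), F->end(), 0.0);

  // native contacts
  for (size_t c = 0; c < S.ni.size(); ++c) {
    int i = S.ni[c], j = S.nj[c];
    double s = S.nsig[c];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double rc = S.native_cut_factor * s;
    if (r2 > rc * rc) continue;
    double r = std::sqrt(r2);
    double sr = s / r;
    double sr2 = sr * sr;
    double sr10 = sr2 * sr2 * sr2 * sr2 * sr2;
    double sr12 = sr10 * sr2;
    double v, dvdr;
    if (S.form == 0) {
      v = 4.0 * S.eps_n * (sr12 - sr10);
      dvdr = 4.0 * S.eps_n * (-12.0 * sr12 + 10.0 * sr10) / r;
    } else {
      v = S.eps_n * (5.0 * sr12 - 6.0 * sr10);
      dvdr = S.eps_n * (-60.0 * sr12 + 60.0 * sr10) / r;
    }
    E.native += v;
    if (F) {
      double fac = -dvdr / r; // force on i along +d
      (*F)[3 * i] += fac * dx;
      (*F)[3 * i + 1] += fac * dy;
      (*F)[3 * i + 2] += fac * dz;
      (*F)[3 * j] -= fac * dx;
      (*F)[3 * j + 1] -= fac * dy;
      (*F)[3 * j + 2] -= fac * dz;
    }
  }

  // non-native repulsion over the Verlet list
  if (plist.stale(pos)) plist.build(pos, S);
  const double rc2 = S.rcut_nn * S.rcut_nn;
  for (size_t c = 0; c < plist.pi.size(); ++c) {
    int i = plist.pi[c], j = plist.pj[c];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) continue;
    if (r2 < 1e-12) {
      if (bad_pair) { bad_pair[0] = i + 1; bad_pair[1] = j + 1; }
      return false;
    }
    double r = std::sqrt(r2);
    double sr = S.sigma_rep / r;
    double sr2 = sr * sr;
    double sr12 = sr2 * sr2 * sr2 * sr2 * sr2 * sr2;
    E.nonnative += 4.0 * S.eps_nn * sr12;
    if (F) {
      double dvdr = -48.0 * S.eps_nn * sr12 / r;
      double fac = -dvdr / r;
      (*F)[3 * i] += fac * dx;
      (*F)[3 * i + 1] += fac * dy;
      (*F)[3 * i + 2] += fac * dz;
      (*F)[3 * j] -= fac * dx;
      (*F)[3 * j + 1] -= fac * dy;
      (*F)[3 * j + 2] -= fac * dz;
    }
  }

  // bonds: k (r - r0)^2
  for (size_t c = 0; c < S.bi.size(); ++c) {
    int i = S.bi[c], j = S.bj[c];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.br0[c];
    E.bond += S.k_bond * dr * dr;
    if (F && r > 1e-12) {
      double fac = -2.0 * S.k_bond * dr / r;
      (*F)[3 * i] += fac * dx;
      (*F)[3 * i + 1] += fac * dy;
      (*F)[3 * i + 2] += fac * dz;
      (*F)[3 * j] -= fac * dx;
      (*F)[3 * j + 1] -= fac * dy;
      (*F)[3 * j + 2] -= fac * dz;
    }
  }

  // angles: k (theta - theta0)^2, vertex j
  for (size_t c = 0; c < S.ai.size(); ++c) {
    int i = S.ai[c], j = S.aj[c], k = S.ak[c];
    Vec3 d = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
              pos[3 * i + 2] - pos[3 * j + 2]};
    Vec3 e = {pos[3 * k] - pos[3 * j], pos[3 * k + 1] - pos[3 * j + 1],
              pos[3 * k + 2] - pos[3 * j + 2]};
    double nd = vnorm(d), ne = vnorm(e);
    if (nd < 1e-12 || ne < 1e-12) continue;
    double cth = vdot(d, e) / (nd * ne);
    if (cth > 1.0) cth = 1.0;
    if (cth < -1.0) cth = -1.0;
    double th = std::acos(cth);
    double dth = th - S.ath0[c];
    E.angle += S.k_angle * dth * dth;
    double sth = std::sqrt(1.0 - cth * cth);
    if (F && sth > 1e-8) {
      double vprime = 2.0 * S.k_angle * dth;
      // dtheta/dr_i = -(e_hat - cth * d_hat) / (nd * sth)
      double coef = vprime / sth;
      Vec3 dhat = vscale(d, 1.0 / nd), ehat = vscale(e, 1.0 / ne);
      Vec3 fi = vscale(vsub(ehat, vscale(dhat, cth)), coef / nd);
      Vec3 fk = vscale(vsub(dhat, vscale(ehat, cth)), coef / ne);
      (*F)[3 * i] += fi.x;
      (*F)[3 * i + 1] += fi.y;
      (*F)[3 * i + 2] += fi.z;
      (*F)[3 * k] += fk.x;
      (*F)[3 * k + 1] += fk.y;
      (*F)[3 * k + 2] += fk.z;
      (*F)[3 * j] -= fi.x + fk.x;
      (*F)[3 * j + 1] -= fi.y + fk.y;
      (*F)[3 * j + 2] -= fi.z + fk.z;
    }
  }

  // dihedrals: k (1 - cos(phi - phi0))
  for (size_t c = 0; c < S.di.size(); ++c) {
    int i = S.di[c], j = S.dj[c], k = S.dk[c], l = S.dl[c];
    Vec3 p1 = {pos[3 * i], pos[3 * i + 1], pos[3 * i + 2]};
    Vec3 p2 = {pos[3 * j], pos[3 * j + 1], pos[3 * j + 2]};
    Vec3 p3 = {pos[3 * k], pos[3 * k + 1], pos[3 * k + 2]};
    Vec3 p4 = {pos[3 * l], pos[3 * l + 1], pos[3 * l + 2]};
    Vec3 b1 = vsub(p2, p1), b2 = vsub(p3, p2), b3 = vsub(p4, p3);
    Vec3 c1 = vcross(b1, b2), c2 = vcross(b2, b3);
    double nb2 = vnorm(b2);
    double nc1sq = vdot(c1, c1), nc2sq = vdot(c2, c2);
    if (nb2 < 1e-12 || nc1sq < 1e-16 || nc2sq < 1e-16) continue;
    double x = vdot(c1, c2);
    double y = vdot(vcross(c1, c2), b2) / nb2;
    double phi = std::atan2(y, x);
    E.dih += S.k_dihedral * (1.0 - std::cos(phi - S.dphi0[c]));
    if (F) {
      double dvdphi = S.k_dihedral * std::sin(phi - S.dphi0[c]);
      // dphi/dr_i = -(|b2|/|c1|^2) c1, dphi/dr_l = +(|b2|/|c2|^2) c2
      Vec3 fi = vscale(c1, dvdphi * nb2 / nc1sq);
      Vec3 fl = vscale(c2, -dvdphi * nb2 / nc2sq);
      // with d1 = dphi/dr_i, d4 = dphi/dr_l:
      // dphi/dr_j = -(1 + t1) d1 + t2 d4, dphi/dr_k = t1 d1 - (1 + t2) d4
      double t1 = vdot(b1, b2) / (nb2 * nb2);
      double t2 = vdot(b3, b2) / (nb2 * nb2);
      Vec3 fj = {-(1 + t1) * fi.x + t2 * fl.x,
                 -(1 + t1) * fi.y + t2 * fl.y,
                 -(1 + t1) * fi.z + t2 * fl.z};
      Vec3 fk = {t1 * fi.x - (1 + t2) * fl.x,
                 t1 * fi.y - (1 + t2) * fl.y,
                 t1 * fi.z - (1 + t2) * fl.z};
      (*F)[3 * i] += fi.x;
      (*F)[3 * i + 1] += fi.y;
      (*F)[3 * i + 2] += fi.z;
      (*F)[3 * j] += fj.x;
      (*F)[3 * j + 1] += fj.y;
      (*F)[3 * j + 2] += fj.z;
      (*F)[3 * k] += fk.x;
      (*F)[3 * k + 1] += fk.y;
      (*F)[3 * k + 2] += fk.z;
      (*F)[3 * l] += fl.x;
      (*F)[3 * l + 1] += fl.y;
      (*F)[3 * l + 2] += fl.z;
    }
  }
  return true;
}

static int count_formed(const std::vector<double> &pos, const GoSystem &S,
                        double lambda) {
  int formed = 0;
  for (size_t c = 0; c < S.ni.size(); ++c) {
    int i = S.ni[c], j = S.nj[c];
    double dx = pos[3 * i] - pos[3 * j];
    double dy = pos[3 * i + 1] - pos[3 * j + 1];
    double dz = pos[3 * i + 2] - pos[3 * j + 2];
    double thr = lambda * S.nsig[c];
    if (dx * dx + dy * dy + dz * dz < thr * thr) ++formed;
  }
  return formed;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix positions, List sys, bool forces) {
  int n = positions.nrow();
  GoSystem S = build_system(n, sys);
  std::vector<double> pos(3 * n);
  for (int i = 0; i < n; ++i) {
    pos[3 * i] = positions(i, 0);
    pos[3 * i + 1] = positions(i, 1);
    pos[3 * i + 2] = positions(i, 2);
  }
  PairList plist;
  EnergyAcc E;
  std::vector<double> F;
  if (forces) F.assign(3 * n, 0.0);
  int bad[2] = {0, 0};
  bool ok = eval_forces(pos, S, plist, E, forces ? &F : nullptr, bad);
  if (!ok)
    stop("overlapping atoms in a non-native pair (atoms %d and %d)", bad[0],
         bad[1]);
  NumericMatrix Fm(n, 3);
  if (forces)
    for (int i = 0; i < n; ++i) {
      Fm(i, 0) = F[3 * i];
      Fm(i, 1) = F[3 * i + 1];
      Fm(i, 2) = F[3 * i + 2];
    }
  return List::create(
      _["total"] = E.total(), _["native_term"] = E.native,
      _["nonnative_term"] = E.nonnative, _["bond_term"] = E.bond,
      _["angle_term"] = E.angle, _["dihedral_term"] = E.dih,
      _["forces"] = Fm);
}

// [[Rcpp::export]]
int cpp_count_formed(NumericMatrix positions, IntegerVector nat_i,
                     IntegerVector nat_j, NumericVector nat_sigma,
                     double lambda) {
  int n = positions.nrow();
  int formed = 0;
  for (int c = 0; c < nat_i.size(); ++c) {
    int i = nat_i[c], j = nat_j[c];
    double dx = positions(i, 0) - positions(j, 0);
    double dy = positions(i, 1) - positions(j, 1);
    double dz = positions(i, 2) - positions(j, 2);
    double thr = lambda * nat_sigma[c];
    if (dx * dx + dy * dy + dz * dz < thr * thr) ++formed;
  }
  (void)n;
  return formed;
}

// BAOAB Langevin integrator. Returns recorded frames, Q series and
// energies. q_stop_high / q_stop_low < 0 disable the respective check.
// Termination: outcome 1 when Q > q_stop_high, 2 when Q <= q_stop_low,
// 0 when the step budget is exhausted, -1 on NaN (error).
// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix positions, NumericMatrix velocities,
                      NumericVector mass, List sys, int n_steps, double dt,
                      double friction, double temperature, int seed,
                      int stride, double lambda, double q_stop_high,
                      double q_stop_low, int record_stride) {
  int n = positions.nrow();
  GoSystem S = build_system(n, sys);
  std::vector<double> pos(3 * n), vel(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    pos[3 * i] = positions(i, 0);
    pos[3 * i + 1] = positions(i, 1);
    pos[3 * i + 2] = positions(i, 2);
    vel[3 * i] = velocities(i, 0);
    vel[3 * i + 1] = velocities(i, 1);
    vel[3 * i + 2] = velocities(i, 2);
  }
  const double kB = 0.0019872041;
  std::vector<double> invm(n), sigv(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = 1.0 / mass[i];
    sigv[i] = std::sqrt(std::max(0.0, kB * temperature * KFAC * invm[i]));
  }
  double c1 = friction > 0 ? std::exp(-friction * dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  PairList plist;
  EnergyAcc E;
  int bad[2] = {0, 0};
  if (!eval_forces(pos, S, plist, E, &F, bad))
    stop("overlapping atoms at step 0 (atoms %d and %d)", bad[0], bad[1]);

  int n_contacts = (int)S.ni.size();
  int nrec = n_steps / record_stride + 1;
  NumericMatrix frames(nrec, 3 * n);
  NumericVector rec_t(nrec), rec_q(nrec), rec_epot(nrec), rec_ekin(nrec);
  int irec = 0;
  auto record = [&](int step) {
    if (irec >= nrec) return;
    for (int i = 0; i < 3 * n; ++i) frames(irec, i) = pos[i];
    rec_t[irec] = step * dt;
    rec_q[irec] =
        n_contacts > 0 ? (double)count_formed(pos, S, lambda) / n_contacts : 0.0;
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] *
            (vel[3 * i] * vel[3 * i] + vel[3 * i + 1] * vel[3 * i + 1] +
             vel[3 * i + 2] * vel[3 * i + 2]);
    rec_ekin[irec] = ke / KFAC;
    rec_epot[irec] = E.total();
    ++irec;
  };
  record(0);

  int outcome = 0;
  int steps_done = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KFAC * invm[i];
      vel[3 * i] += a * F[3 * i];
      vel[3 * i + 1] += a * F[3 * i + 1];
      vel[3 * i + 2] += a * F[3 * i + 2];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) pos[i] += 0.5 * dt * vel[i];
    // O: thermostat
    if (friction > 0) {
      for (int i = 0; i < n; ++i) {
        vel[3 * i] = c1 * vel[3 * i] + c2 * sigv[i] * gauss(rng);
        vel[3 * i + 1] = c1 * vel[3 * i + 1] + c2 * sigv[i] * gauss(rng);
        vel[3 * i + 2] = c1 * vel[3 * i + 2] + c2 * sigv[i] * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) pos[i] += 0.5 * dt * vel[i];
    // force update + B: half kick
    if (!eval_forces(pos, S, plist, E, &F, bad))
      stop("overlapping atoms at step %d (atoms %d and %d)", step, bad[0],
           bad[1]);
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KFAC * invm[i];
      vel[3 * i] += a * F[3 * i];
      vel[3 * i + 1] += a * F[3 * i + 1];
      vel[3 * i + 2] += a * F[3 * i + 2];
    }
    steps_done = step;

    if (step % record_stride == 0) record(step);
    if (step % stride == 0) {
      if (!std::isfinite(pos[0]) || !std::isfinite(pos[3 * n - 1]))
        stop("position overflow/NaN at step %d", step);
      if (q_stop_high >= 0 || q_stop_low >= 0) {
        double q = n_contacts > 0
                       ? (double)count_formed(pos, S, lambda) / n_contacts
                       : 0.0;
        if (q_stop_high >= 0 && q > q_stop_high) {
          outcome = 1;
          break;
        }
        if (q_stop_low >= 0 && q <= q_stop_low) {
          outcome = 2;
          break;
        }
      }
    }
  }

  // final state always recorded (may duplicate last strided record)
  if (irec < nrec && (steps_done % record_stride) != 0) record(steps_done);

  NumericMatrix out_frames(irec, 3 * n);
  for (int r = 0; r < irec; ++r)
    for (int i = 0; i < 3 * n; ++i) out_frames(r, i) = frames(r, i);
  NumericMatrix fpos(n, 3), fvel(n, 3);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = pos[3 * i];
    fpos(i, 1) = pos[3 * i + 1];
    fpos(i, 2) = pos[3 * i + 2];
    fvel(i, 0) = vel[3 * i];
    fvel(i, 1) = vel[3 * i + 1];
    fvel(i, 2) = vel[3 * i + 2];
  }
  return List::create(
      _["frames"] = out_frames, _["times"] = rec_t[Range(0, irec - 1)],
      _["q"] = rec_q[Range(0, irec - 1)],
      _["epot"] = rec_epot[Range(0, irec - 1)],
      _["ekin"] = rec_ekin[Range(0, irec - 1)], _["positions"] = fpos,
      _["velocities"] = fvel, _["outcome"] = outcome,
      _["steps"] = steps_done);
}
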