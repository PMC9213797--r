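// Compiled core: spline evaluation, pairwise energies/forces, RPY diffusion,
// SHAKE-style bond projection, and the overdamped BD propagator.
// Units throughout: A, ps, kcal/mol, elementary charges; kB in kcal/mol/K.

#include <RcppArmadillo.h>
#include "spline.h"

using namespace Rcpp;

static const double KB = 0.0019872041;        // kcal mol^-1 K^-1
static const double COUL = 332.0637;          // kcal A mol^-1 e^-2
// converts kT[kcal/mol] / (viscosity[cP] * length[A]) to A^2/ps
static const double VISC_CONV = 4184.0 / 6.02214076e23 / 1e-13 * 1e8;

// ---------------------------------------------------------------------------
// spline evaluation (shared by the R surface and the engine)

static std::vector<Spline> build_splines(const List &tables) {
  std::vector<Spline> out;
  out.reserve(tables.size());
  for (int t = 0; t < tables.size(); ++t) {
    List tab = tables[t];
    Spline s;
    s.kind = as<int>(tab["kind"]);
    s.x = as<std::vector<double>>(tab["x"]);
    s.y = as<std::vector<double>>(tab["y"]);
    s.setup();
    out.push_back(std::move(s));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_spline_eval(NumericVector x, NumericVector y, int kind,
                              NumericVector xout) {
  Spline s;
  s.kind = kind;
  s.x = as<std::vector<double>>(x);
  s.y = as<std::vector<double>>(y);
  s.setup();
  NumericMatrix out(xout.size(), 2);
  for (int i = 0; i < xout.size(); ++i) {
    double e, d;
    s.eval(xout[i], e, d);
    out(i, 0) = e;
    out(i, 1) = d;
  }
  colnames(out) = CharacterVector::create("energy", "derivative");
  return out;
}

// ---------------------------------------------------------------------------
// system container unpacked from R

struct SysData {
  arma::mat pos;              // N x 3
  arma::ivec chain, resi;     // chain id (1-based ok), residue index in chain
  arma::vec charge, radius;
  arma::imat bonds;           // M x 2, 0-based
  arma::vec bond_target;
  arma::ivec bond_tab;        // table id or -1
  arma::imat angles;          // A x 3
  arma::ivec angle_tab;
  arma::imat dihedrals;       // D x 4
  arma::ivec dih_tab;
  arma::imat ntab;            // N x N nonbonded table id or -1
  arma::imat restr;           // R x 2
  arma::vec restr_cap, restr_k;
  double s, lambda_d, dielectric, temperature, viscosity;
  bool elec_on;
};

static SysData unpack_sys(const List &sys) {
  SysData d;
  d.pos = as<arma::mat>(sys["pos"]);
  d.chain = as<arma::ivec>(sys["chain"]);
  d.resi = as<arma::ivec>(sys["resi"]);
  d.charge = as<arma::vec>(sys["charge"]);
  d.radius = as<arma::vec>(sys["radius"]);
  d.bonds = as<arma::imat>(sys["bonds"]);
  d.bond_target = as<arma::vec>(sys["bond_target"]);
  d.bond_tab = as<arma::ivec>(sys["bond_tab"]);
  d.angles = as<arma::imat>(sys["angles"]);
  d.angle_tab = as<arma::ivec>(sys["angle_tab"]);
  d.dihedrals = as<arma::imat>(sys["dihedrals"]);
  d.dih_tab = as<arma::ivec>(sys["dih_tab"]);
  d.ntab = as<arma::imat>(sys["ntab"]);
  d.restr = as<arma::imat>(sys["restr"]);
  d.restr_cap = as<arma::vec>(sys["restr_cap"]);
  d.restr_k = as<arma::vec>(sys["restr_k"]);
  d.s = as<double>(sys["scaling_factor"]);
  d.lambda_d = as<double>(sys["lambda_d"]);
  d.dielectric = as<double>(sys["dielectric"]);
  d.temperature = as<double>(sys["temperature"]);
  d.viscosity = as<double>(sys["viscosity"]);
  d.elec_on = as<bool>(sys["elec_on"]);
  return d;
}

// 1-2 / 1-3 exclusion: beads closer than 3 bonds apart on the same chain
static inline bool excluded(const SysData &d, int i, int j) {
  return d.chain[i] == d.chain[j] && std::abs(d.resi[i] - d.resi[j]) <= 2;
}

// ---------------------------------------------------------------------------
// energy/force kernels

static void nonbonded_terms(const SysData &d, const std::vector<Spline> &sp,
                            const arma::mat &pos, arma::mat &F,
                            double &e_table, double &e_elec) {
  const int N = pos.n_rows;
  e_table = 0.0;
  e_elec = 0.0;
  F.zeros(N, 3);
  const bool do_elec = d.elec_on && d.lambda_d > 0.0;
  const double *px = pos.colptr(0), *py = pos.colptr(1), *pz = pos.colptr(2);
  double *fx = F.colptr(0), *fy = F.colptr(1), *fz = F.colptr(2);
  for (int i = 0; i < N - 1; ++i) {
    const double xi = px[i], yi = py[i], zi = pz[i], qi = d.charge[i];
    for (int j = i + 1; j < N; ++j) {
      if (excluded(d, i, j)) continue;
      const int tid = d.ntab(i, j);
      const double qq = qi * d.charge[j];
      if (tid < 0 && (!do_elec || qq == 0.0)) continue;
      const double dx = xi - px[j], dy = yi - py[j], dz = zi - pz[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= 0.0) stop("coincident beads %d and %d in nonbonded evaluation",
                          i + 1, j + 1);
      const double r = std::sqrt(r2);
      double dudr = 0.0;
      if (tid >= 0 && r < sp[tid].x.back()) {
        double e, dd;
        sp[tid].eval(r, e, dd);
        e_table += d.s * e;
        dudr += d.s * dd;
      }
      if (do_elec && qq != 0.0) {
        const double u = COUL * qq * std::exp(-r / d.lambda_d) /
                         (d.dielectric * r);
        e_elec += u;
        dudr += -u * (1.0 / d.lambda_d + 1.0 / r);
      }
      if (dudr == 0.0) continue;
      // F_i = -dU/dr * rhat
      const double g = -dudr / r;
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }
}

static void bonded_terms(const SysData &d, const std::vector<Spline> &sp,
                         const arma::mat &pos, bool include_bond_tables,
                         arma::mat &F, double &e_bond, double &e_angle,
                         double &e_dih, double &e_restr) {
  const int N = pos.n_rows;
  e_bond = e_angle = e_dih = e_restr = 0.0;
  F.zeros(N, 3);

  if (include_bond_tables) {
    for (arma::uword b = 0; b < d.bonds.n_rows; ++b) {
      const int tid = d.bond_tab[b];
      if (tid < 0) continue;
      const int i = d.bonds(b, 0), j = d.bonds(b, 1);
      arma::rowvec rij = pos.row(i) - pos.row(j);
      const double r = arma::norm(rij);
      double e, dd;
      sp[tid].eval(r, e, dd);
      e_bond += e;
      arma::rowvec f = (-dd / r) * rij;
      F.row(i) += f;
      F.row(j) -= f;
    }
  }

  const double RAD2DEG = 180.0 / M_PI;
  for (arma::uword a = 0; a < d.angles.n_rows; ++a) {
    const int tid = d.angle_tab[a];
    if (tid < 0) continue;
    const int i = d.angles(a, 0), j = d.angles(a, 1), k = d.angles(a, 2);
    arma::rowvec rij = pos.row(i) - pos.row(j);
    arma::rowvec rkj = pos.row(k) - pos.row(j);
    const double nij = arma::norm(rij), nkj = arma::norm(rkj);
    double ct = arma::dot(rij, rkj) / (nij * nkj);
    ct = std::max(-1.0, std::min(1.0, ct));
    const double theta = std::acos(ct);
    const double st = std::sqrt(std::max(1.0 - ct * ct, 1e-16));
    double e, dd_deg;
    sp[tid].eval(theta * RAD2DEG, e, dd_deg);
    e_angle += e;
    const double dudt = dd_deg * RAD2DEG;  // per radian
    // F = -dU/dtheta * dtheta/dr with dtheta/dr = -(1/sin) dcos/dr
    arma::rowvec fi = (dudt / (nij * st)) * (rkj / nkj - ct * rij / nij);
    arma::rowvec fk = (dudt / (nkj * st)) * (rij / nij - ct * rkj / nkj);
    F.row(i) += fi;
    F.row(k) += fk;
    F.row(j) -= fi + fk;
  }

  for (arma::uword t = 0; t < d.dihedrals.n_rows; ++t) {
    const int tid = d.dih_tab[t];
    if (tid < 0) continue;
    const int i = d.dihedrals(t, 0), j = d.dihedrals(t, 1);
    const int k = d.dihedrals(t, 2), l = d.dihedrals(t, 3);
    arma::rowvec b1 = pos.row(j) - pos.row(i);
    arma::rowvec b2 = pos.row(k) - pos.row(j);
    arma::rowvec b3 = pos.row(l) - pos.row(k);
    arma::rowvec n1 = arma::cross(b1, b2);
    arma::rowvec n2 = arma::cross(b2, b3);
    const double nb2 = arma::norm(b2);
    const double n1sq = arma::dot(n1, n1), n2sq = arma::dot(n2, n2);
    if (n1sq < 1e-16 || n2sq < 1e-16) continue;  // collinear, torsion undefined
    const double phi = std::atan2(arma::dot(arma::cross(n1, n2), b2) / nb2,
                                  arma::dot(n1, n2));
    double e, dd_deg;
    sp[tid].eval(phi * RAD2DEG, e, dd_deg);
    e_dih += e;
    const double dudphi = dd_deg * RAD2DEG;
    arma::rowvec fi = (dudphi * nb2 / n1sq) * n1;
    arma::rowvec fl = (-dudphi * nb2 / n2sq) * n2;
    const double tb = arma::dot(b1, b2) / (nb2 * nb2);
    const double sb = arma::dot(b3, b2) / (nb2 * nb2);
    arma::rowvec fj = -fi - tb * fi + sb * fl;
    arma::rowvec fk = -fl + tb * fi - sb * fl;
    F.row(i) += fi;
    F.row(j) += fj;
    F.row(k) += fk;
    F.row(l) += fl;
  }

  for (arma::uword rr = 0; rr < d.restr.n_rows; ++rr) {
    const int i = d.restr(rr, 0), j = d.restr(rr, 1);
    arma::rowvec rij = pos.row(i) - pos.row(j);
    const double r = arma::norm(rij);
    const double cap = d.restr_cap[rr], kk = d.restr_k[rr];
    if (r <= cap || r == 0.0) continue;
    const double ext = r - cap;
    e_restr += 0.5 * kk * ext * ext;
    arma::rowvec f = (-kk * ext / r) * rij;  // pulls i toward j
    F.row(i) += f;
    F.row(j) -= f;
  }
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys, List tables, bool include_bond_tables = true) {
  SysData d = unpack_sys(sys);
  std::vector<Spline> sp = build_splines(tables);
  arma::mat Fnb, Fb;
  double enb, eel, ebond, eangle, edih, erestr;
  nonbonded_terms(d, sp, d.pos, Fnb, enb, eel);
  bonded_terms(d, sp, d.pos, include_bond_tables, Fb, ebond, eangle, edih,
               erestr);
  return List::create(
      _["bond"] = ebond, _["angle"] = eangle, _["dihedral"] = edih,
      _["nonbonded_table"] = enb, _["electrostatic"] = eel,
      _["restraint"] = erestr, _["forces"] = wrap(Fnb + Fb));
}

// ---------------------------------------------------------------------------
// Rotne-Prager-Yamakawa diffusion matrix (overlap-corrected), A^2/ps

// [[Rcpp::export]]
arma::mat cpp_rpy_matrix(const arma::mat &pos, const arma::vec &radius,
                         double temperature, double viscosity) {
  const int N = pos.n_rows;
  const double kT = KB * temperature;
  arma::mat D(3 * N, 3 * N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    const double Dii = VISC_CONV * kT / (6.0 * M_PI * viscosity * radius[i]);
    for (int c = 0; c < 3; ++c) D(3 * i + c, 3 * i + c) = Dii;
  }
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      arma::vec rij = (pos.row(i) - pos.row(j)).t();
      const double r = arma::norm(rij);
      arma::mat blk(3, 3);
      const double ai = radius[i], aj = radius[j];
      if (r >= ai + aj) {
        const double pref = VISC_CONV * kT / (8.0 * M_PI * viscosity * r);
        const double asq = (ai * ai + aj * aj) / (r * r);
        arma::mat rr = rij * rij.t() / (r * r);
        blk = pref * ((1.0 + asq / 3.0) * arma::eye(3, 3) +
                      (1.0 - asq) * rr);
      } else {
        // overlapping branch (equal-radius form with the mean radius)
        const double a = 0.5 * (ai + aj);
        const double pref = VISC_CONV * kT / (6.0 * M_PI * viscosity * a);
        arma::mat rr = (r > 0.0) ? arma::mat(rij * rij.t() / (r * r))
                                 : arma::mat(3, 3, arma::fill::zeros);
        blk = pref * ((1.0 - 9.0 * r / (32.0 * a)) * arma::eye(3, 3) +
                      (3.0 * r / (32.0 * a)) * rr);
      }
      D.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = blk;
      D.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = blk.t();
    }
  }
  return D;
}

// ---------------------------------------------------------------------------
// SHAKE-style pairwise projection of bond constraints

static bool shake_sweeps(arma::mat &pos, const arma::imat &bonds,
                         const arma::vec &targets, double tol, int max_sweeps,
                         int &sweeps, int &worst_bond, double &worst_dev) {
  const int M = bonds.n_rows;
  double *px = pos.colptr(0), *py = pos.colptr(1), *pz = pos.colptr(2);
  // over-relaxation accelerates the Gauss-Seidel sweeps on chain topologies
  const double omega = 1.4;
  for (sweeps = 0; sweeps < max_sweeps; ++sweeps) {
    double maxdev = 0.0;
    int maxb = 0;
    for (int b = 0; b < M; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      const double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double dev = std::fabs(r - targets[b]) / targets[b];
      if (dev > maxdev) { maxdev = dev; maxb = b; }
      if (dev > tol && r > 0.0) {
        // symmetric move along the current bond direction (equal weights)
        const double g = omega * 0.5 * (r - targets[b]) / r;
        px[i] -= g * dx; py[i] -= g * dy; pz[i] -= g * dz;
        px[j] += g * dx; py[j] += g * dy; pz[j] += g * dz;
      }
    }
    if (maxdev <= tol) {
      worst_bond = maxb;
      worst_dev = maxdev;
      return true;
    }
    worst_bond = maxb;
    worst_dev = maxdev;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_shake(NumericMatrix positions, IntegerMatrix bonds,
               NumericVector targets, double tol = 1e-4,
               int max_sweeps = 500) {
  arma::mat pos = as<arma::mat>(positions);
  arma::imat b = as<arma::imat>(bonds);
  arma::vec t = as<arma::vec>(targets);
  int sweeps = 0, worst = 0;
  double dev = 0.0;
  bool ok = shake_sweeps(pos, b, t, tol, max_sweeps, sweeps, worst, dev);
  return List::create(_["positions"] = wrap(pos), _["sweeps"] = sweeps + 1,
                      _["converged"] = ok, _["worst_bond"] = worst + 1,
                      _["worst_deviation"] = dev);
}

// ---------------------------------------------------------------------------
// BD propagator (Ermak-McCammon, divergence-free mobility)

// [[Rcpp::export]]
List cpp_run_bd(List sys, List tables, List params) {
  SysData d = unpack_sys(sys);
  std::vector<Spline> sp = build_splines(tables);

  const double dt = as<double>(params["dt"]);
  const int max_steps = as<int>(params["max_steps"]);
  const int stride = as<int>(params["snapshot_stride"]);
  const bool hi_on = as<bool>(params["hi_on"]);
  const int hi_int = as<int>(params["hi_update_interval"]);
  const int f_int = as<int>(params["force_update_interval"]);
  const bool constraints_on = as<bool>(params["constraints_on"]);
  const double shake_tol = as<double>(params["shake_tol"]);
  const int shake_max = as<int>(params["shake_max_sweeps"]);
  const bool record_energy = as<bool>(params["record_energy"]);

  const int N = d.pos.n_rows;
  const double kT = KB * d.temperature;
  const int n_snap = max_steps / stride + 1;

  arma::mat pos = d.pos;
  arma::cube coords(N, 3, n_snap);
  arma::vec times(n_snap), e_snap(record_energy ? n_snap : 0);

  // diffusion state
  arma::vec Dfree(N);
  for (int i = 0; i < N; ++i)
    Dfree[i] = VISC_CONV * kT / (6.0 * M_PI * d.viscosity * d.radius[i]);
  arma::mat Dmat, Lchol;

  arma::mat Fnb(N, 3, arma::fill::zeros), Fb(N, 3, arma::fill::zeros);
  double enb = 0.0, eel = 0.0, ebond, eangle, edih, erestr;

  auto record = [&](int slot, int step) {
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) {
        if (!std::isfinite(pos(i, c)))
          stop("non-finite position at step %d (bead %d)", step, i + 1);
        coords(i, c, slot) = pos(i, c);
      }
    times[slot] = step * dt;
    if (record_energy) {
      arma::mat tmp;
      double b2, a2, d2, r2, nb2, el2;
      nonbonded_terms(d, sp, pos, tmp, nb2, el2);
      bonded_terms(d, sp, pos, !constraints_on, tmp, b2, a2, d2, r2);
      e_snap[slot] = b2 + a2 + d2 + d.s * 0.0 + nb2 + el2 + r2;
    }
  };

  record(0, 0);
  int slot = 1;

  for (int step = 1; step <= max_steps; ++step) {
    if (step % 20000 == 0) checkUserInterrupt();

    if (hi_on && ((step - 1) % hi_int == 0)) {
      Dmat = cpp_rpy_matrix(pos, d.radius, d.temperature, d.viscosity);
      if (!arma::chol(Lchol, Dmat, "lower")) {
        // PSD up to roundoff: regularize minimally and retry once
        arma::mat Dreg = Dmat + 1e-10 * arma::eye(3 * N, 3 * N);
        if (!arma::chol(Lchol, Dreg, "lower"))
          stop("diffusion matrix factorization failed at step %d", step);
      }
    }
    if ((step - 1) % f_int == 0)
      nonbonded_terms(d, sp, pos, Fnb, enb, eel);
    bonded_terms(d, sp, pos, !constraints_on, Fb, ebond, eangle, edih, erestr);

    arma::mat F = Fnb + Fb;
    arma::mat trial(N, 3);
    if (hi_on) {
      arma::vec f(3 * N), z(3 * N);
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) f[3 * i + c] = F(i, c);
      for (int k = 0; k < 3 * N; ++k) z[k] = norm_rand();
      arma::vec dx = (dt / kT) * (Dmat * f) + std::sqrt(2.0 * dt) * (Lchol * z);
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c) trial(i, c) = pos(i, c) + dx[3 * i + c];
    } else {
      for (int i = 0; i < N; ++i) {
        const double drift = dt * Dfree[i] / kT;
        const double sig = std::sqrt(2.0 * Dfree[i] * dt);
        for (int c = 0; c < 3; ++c)
          trial(i, c) = pos(i, c) + drift * F(i, c) + sig * norm_rand();
      }
    }

    if (constraints_on && d.bonds.n_rows > 0) {
      int sweeps, worst;
      double dev;
      if (!shake_sweeps(trial, d.bonds, d.bond_target, shake_tol, shake_max,
                        sweeps, worst, dev))
        stop("bond constraints failed to converge at step %d "
             "(worst bond %d, relative deviation %g)", step, worst + 1, dev);
    }
    pos = trial;

    if (step % stride == 0) record(slot++, step);
  }

  return List::create(_["times"] = wrap(times), _["coords"] = wrap(coords),
                      _["energies"] = wrap(e_snap));
}
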