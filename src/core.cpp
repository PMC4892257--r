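#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <map>
using namespace Rcpp;

// Species order shared with the R side (see species_names()):
// 0 N, 1 D, 2 J, 3 I, 4 miR34, 5 mS, 6 S, 7 miR200, 8 mZ, 9 Z, 10 F
static const int NSPEC = 11;
// Environment columns: 0 N_ext, 1 D_ext, 2 J_ext, 3 sD_ext, 4 sJ_ext, 5 I_ext
static const int NENV = 6;

// shifted Hill: 1 at X = 0, lambda at saturation
static inline double hshift(double X, double X0, double n, double lam) {
  double r = std::pow(X / X0, n);
  return (1.0 + lam * r) / (1.0 + r);
}

struct Hill { double X0, n, lam; };

// combinatorial microRNA-mRNA binding ladder
struct Mir {
  double mu0;
  int sites;
  std::vector<double> l, gm, gu, binom;
};

struct Pars {
  double gN, gD, gJ, kc, kt, affD, affJ, gammaN, gammaD, gammaJ, gammaI;
  double gu34, gms, gs, gu200, gmz, gz;
  double gammau34, gammams, gammas, gammau200, gammamz, gammaz;
  double gF, gammaF;
  bool fringe;
  // hill rows in fixed order
  Hill I_N, I_D, I_J, Z_u200, S_u200, Z_mz, S_mz, S_u34, Z_u34, S_ms,
       I_ms, Iext_ms, I_F, F_delta, F_jagged;
  Mir mir34_N, mir34_D, mir200_J, mir34_ms, mir200_mz;
};

static Hill get_hill(NumericMatrix h, int row) {
  Hill out; out.X0 = h(row, 0); out.n = h(row, 1); out.lam = h(row, 2);
  return out;
}

static Mir get_mir(List m) {
  Mir out;
  out.mu0 = as<double>(m["mu0"]);
  NumericVector l = m["l"], gm = m["gm"], gu = m["gu"];
  out.sites = l.size() - 1;
  out.l.assign(l.begin(), l.end());
  out.gm.assign(gm.begin(), gm.end());
  out.gu.assign(gu.begin(), gu.end());
  out.binom.resize(out.sites + 1);
  out.binom[0] = 1.0;
  for (int i = 1; i <= out.sites; ++i)
    out.binom[i] = out.binom[i - 1] * (out.sites - i + 1) / i;
  return out;
}

static Pars get_pars(List cp) {
  Pars p;
  NumericVector s = cp["scalars"];
  CharacterVector nm = s.names();
  std::map<std::string, double> sm;
  for (int i = 0; i < s.size(); ++i) sm[as<std::string>(nm[i])] = s[i];
  p.gN = sm["gN"]; p.gD = sm["gD"]; p.gJ = sm["gJ"];
  p.kc = sm["kc"]; p.kt = sm["kt"];
  p.affD = sm["affinityD"]; p.affJ = sm["affinityJ"];
  p.gammaN = sm["gammaN"]; p.gammaD = sm["gammaD"]; p.gammaJ = sm["gammaJ"];
  p.gammaI = sm["gammaI"];
  p.gu34 = sm["gu34"]; p.gms = sm["gms"]; p.gs = sm["gs"];
  p.gu200 = sm["gu200"]; p.gmz = sm["gmz"]; p.gz = sm["gz"];
  p.gammau34 = sm["gammau34"]; p.gammams = sm["gammams"]; p.gammas = sm["gammas"];
  p.gammau200 = sm["gammau200"]; p.gammamz = sm["gammamz"]; p.gammaz = sm["gammaz"];
  p.gF = sm["gF"]; p.gammaF = sm["gammaF"];
  p.fringe = sm["fringe"] > 0.5;
  NumericMatrix h = cp["hills"];
  p.I_N = get_hill(h, 0);  p.I_D = get_hill(h, 1);  p.I_J = get_hill(h, 2);
  p.Z_u200 = get_hill(h, 3); p.S_u200 = get_hill(h, 4);
  p.Z_mz = get_hill(h, 5); p.S_mz = get_hill(h, 6);
  p.S_u34 = get_hill(h, 7); p.Z_u34 = get_hill(h, 8); p.S_ms = get_hill(h, 9);
  p.I_ms = get_hill(h, 10); p.Iext_ms = get_hill(h, 11);
  p.I_F = get_hill(h, 12); p.F_delta = get_hill(h, 13); p.F_jagged = get_hill(h, 14);
  List mir = cp["mir"];
  p.mir34_N = get_mir(mir["mir34_N"]);
  p.mir34_D = get_mir(mir["mir34_D"]);
  p.mir200_J = get_mir(mir["mir200_J"]);
  p.mir34_ms = get_mir(mir["mir34_ms"]);
  p.mir200_mz = get_mir(mir["mir200_mz"]);
  return p;
}

// occupancy weights M_i(mu) = C(n,i) (mu/mu0)^i / (1 + mu/mu0)^n
static inline void mir_eval(const Mir& m, double mu, double& L, double& Ym, double& Yu) {
  double x = mu / m.mu0;
  double denom = std::pow(1.0 + x, m.sites);
  L = 0.0; Ym = 0.0; Yu = 0.0;
  double xi = 1.0;
  for (int i = 0; i <= m.sites; ++i) {
    double Mi = m.binom[i] * xi / denom;
    L += m.l[i] * Mi;
    Ym += m.gm[i] * Mi;
    Yu += i * m.gu[i] * Mi;
    xi *= x;
  }
}

static inline void rhs_cell(const double* y, const double* env, const Pars& p, double* dy) {
  const double N = y[0], D = y[1], J = y[2], I = y[3];
  const double u34 = y[4], ms = y[5], S = y[6];
  const double u200 = y[7], mz = y[8], Z = y[9], F = y[10];
  const double Next = env[0], Dext = env[1], Jext = env[2];
  const double sDext = env[3], sJext = env[4], Iext = env[5];

  // ligand-specific trans affinities; Fringe glycosylation scales the
  // Delta affinity up and the Jagged affinity down
  double fD = p.affD, fJ = p.affJ;
  if (p.fringe) {
    fD *= hshift(F, p.F_delta.X0, p.F_delta.n, p.F_delta.lam);
    fJ *= hshift(F, p.F_jagged.X0, p.F_jagged.n, p.F_jagged.lam);
  }
  const double ktD = p.kt * fD, ktJ = p.kt * fJ;
  const double kcD = p.kc, kcJ = p.kc;

  double L34N, L34D, L200J, dum1, dum2;
  mir_eval(p.mir34_N, u34, L34N, dum1, dum2);
  mir_eval(p.mir34_D, u34, L34D, dum1, dum2);
  mir_eval(p.mir200_J, u200, L200J, dum1, dum2);
  double L34ms, Ym34, Yu34, L200mz, Ym200, Yu200;
  mir_eval(p.mir34_ms, u34, L34ms, Ym34, Yu34);
  mir_eval(p.mir200_mz, u200, L200mz, Ym200, Yu200);

  // trans-activation: receptor consumed by external (juxtacrine + soluble) ligand
  const double sig = ktD * N * (Dext + sDext) + ktJ * N * (Jext + sJext);

  dy[0] = p.gN * hshift(I, p.I_N.X0, p.I_N.n, p.I_N.lam) * L34N
          - kcD * N * D - kcJ * N * J - sig - p.gammaN * N;
  dy[1] = p.gD * hshift(I, p.I_D.X0, p.I_D.n, p.I_D.lam) * L34D
          - kcD * N * D - ktD * D * Next - p.gammaD * D;
  dy[2] = p.gJ * hshift(I, p.I_J.X0, p.I_J.n, p.I_J.lam) * L200J
          - kcJ * N * J - ktJ * J * Next - p.gammaJ * J;
  dy[3] = sig - p.gammaI * I;
  dy[4] = p.gu34 * hshift(S, p.S_u34.X0, p.S_u34.n, p.S_u34.lam)
                 * hshift(Z, p.Z_u34.X0, p.Z_u34.n, p.Z_u34.lam)
          - ms * Yu34 - p.gammau34 * u34;
  dy[5] = p.gms * hshift(S, p.S_ms.X0, p.S_ms.n, p.S_ms.lam)
                * hshift(I, p.I_ms.X0, p.I_ms.n, p.I_ms.lam)
                * hshift(Iext, p.Iext_ms.X0, p.Iext_ms.n, p.Iext_ms.lam)
          - ms * Ym34 - p.gammams * ms;
  dy[6] = p.gs * ms * L34ms - p.gammas * S;
  dy[7] = p.gu200 * hshift(S, p.S_u200.X0, p.S_u200.n, p.S_u200.lam)
                  * hshift(Z, p.Z_u200.X0, p.Z_u200.n, p.Z_u200.lam)
          - mz * Yu200 - p.gammau200 * u200;
  dy[8] = p.gmz * hshift(S, p.S_mz.X0, p.S_mz.n, p.S_mz.lam)
                * hshift(Z, p.Z_mz.X0, p.Z_mz.n, p.Z_mz.lam)
          - mz * Ym200 - p.gammamz * mz;
  dy[9] = p.gz * mz * L200mz - p.gammaz * Z;
  dy[10] = p.fringe
           ? p.gF * hshift(I, p.I_F.X0, p.I_F.n, p.I_F.lam) - p.gammaF * F
           : 0.0;
}

static void check_finite(const double* y, double t, int cell) {
  for (int k = 0; k < NSPEC; ++k) {
    if (!std::isfinite(y[k]))
      stop("integration failure: species %d non-finite at t = %f h (cell %d)",
           k + 1, t, cell + 1);
  }
}

// one RK4 step for a single cell with frozen environment, then clamp at zero
static inline void rk4_step(double* y, const double* env, const Pars& p, double dt) {
  double k1[NSPEC], k2[NSPEC], k3[NSPEC], k4[NSPEC], tmp[NSPEC];
  rhs_cell(y, env, p, k1);
  for (int k = 0; k < NSPEC; ++k) tmp[k] = y[k] + 0.5 * dt * k1[k];
  rhs_cell(tmp, env, p, k2);
  for (int k = 0; k < NSPEC; ++k) tmp[k] = y[k] + 0.5 * dt * k2[k];
  rhs_cell(tmp, env, p, k3);
  for (int k = 0; k < NSPEC; ++k) tmp[k] = y[k] + dt * k3[k];
  rhs_cell(tmp, env, p, k4);
  for (int k = 0; k < NSPEC; ++k) {
    y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    if (y[k] < 0.0) y[k] = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_rhs(NumericMatrix states, NumericMatrix env, List cp) {
  Pars p = get_pars(cp);
  int n = states.nrow();
  if (states.ncol() != NSPEC) stop("states must have %d columns", NSPEC);
  NumericMatrix out(n, NSPEC);
  std::vector<double> y(NSPEC), e(NENV), dy(NSPEC);
  for (int i = 0; i < n; ++i) {
    int ie = (env.nrow() == 1) ? 0 : i;
    for (int k = 0; k < NSPEC; ++k) y[k] = states(i, k);
    for (int k = 0; k < NENV; ++k) e[k] = env(ie, k);
    rhs_cell(y.data(), e.data(), p, dy.data());
    for (int k = 0; k < NSPEC; ++k) out(i, k) = dy[k];
  }
  return out;
}

// Integrate each row independently under a fixed environment; optionally record
// the state at the requested times (which are snapped to the dt grid).
// [[Rcpp::export]]
List cpp_integrate(NumericMatrix states, NumericMatrix env, List cp,
                   double t_end, double dt, NumericVector record_times) {
  Pars p = get_pars(cp);
  int n = states.nrow();
  int nsteps = (int) std::lround(t_end / dt);
  NumericMatrix cur = clone(states);
  int nrec = record_times.size();
  std::vector<int> rec_step(nrec);
  for (int r = 0; r < nrec; ++r)
    rec_step[r] = (int) std::lround(record_times[r] / dt);
  List snaps(nrec);
  NumericVector snap_t(nrec);
  std::vector<double> y(NSPEC), e(NENV);
  int next_rec = 0;
  // record at t = 0 if requested
  while (next_rec < nrec && rec_step[next_rec] == 0) {
    snaps[next_rec] = clone(cur);
    snap_t[next_rec] = 0.0;
    ++next_rec;
  }
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      int ie = (env.nrow() == 1) ? 0 : i;
      for (int k = 0; k < NSPEC; ++k) y[k] = cur(i, k);
      for (int k = 0; k < NENV; ++k) e[k] = env(ie, k);
      rk4_step(y.data(), e.data(), p, dt);
      check_finite(y.data(), s * dt, i);
      for (int k = 0; k < NSPEC; ++k) cur(i, k) = y[k];
    }
    while (next_rec < nrec && rec_step[next_rec] == s) {
      snaps[next_rec] = clone(cur);
      snap_t[next_rec] = s * dt;
      ++next_rec;
    }
  }
  return List::create(_["final"] = cur, _["times"] = snap_t, _["snapshots"] = snaps);
}

// Integrate until the relative change of every row over a trailing window is
// below reltol, or until t_max. Returns final states plus per-row convergence.
// clamp: 0-based indices of species held fixed at their initial values
// (quasi-steady relaxation of the remaining species).
// [[Rcpp::export]]
List cpp_integrate_converge(NumericMatrix states, NumericMatrix env, List cp,
                            double t_max, double dt, double window, double reltol,
                            IntegerVector clamp) {
  Pars p = get_pars(cp);
  int n = states.nrow();
  int nsteps = (int) std::lround(t_max / dt);
  int wsteps = std::max(1, (int) std::lround(window / dt));
  NumericMatrix cur = clone(states);
  NumericMatrix prev = clone(states);
  LogicalVector conv(n, false);
  NumericVector t_conv(n, NA_REAL);
  std::vector<double> y(NSPEC), e(NENV);
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      if (conv[i]) continue;
      int ie = (env.nrow() == 1) ? 0 : i;
      for (int k = 0; k < NSPEC; ++k) y[k] = cur(i, k);
      for (int k = 0; k < NENV; ++k) e[k] = env(ie, k);
      rk4_step(y.data(), e.data(), p, dt);
      for (int c = 0; c < clamp.size(); ++c) y[clamp[c]] = states(i, clamp[c]);
      check_finite(y.data(), s * dt, i);
      for (int k = 0; k < NSPEC; ++k) cur(i, k) = y[k];
    }
    if (s % wsteps == 0) {
      bool all_conv = true;
      for (int i = 0; i < n; ++i) {
        if (conv[i]) continue;
        double rel = 0.0;
        for (int k = 0; k < NSPEC; ++k) {
          double d = std::fabs(cur(i, k) - prev(i, k)) /
                     std::max(std::fabs(cur(i, k)), 1.0);
          if (d > rel) rel = d;
        }
        if (rel < reltol) { conv[i] = true; t_conv[i] = s * dt; }
        else all_conv = false;
        for (int k = 0; k < NSPEC; ++k) prev(i, k) = cur(i, k);
      }
      if (all_conv) break;
    }
  }
  return List::create(_["final"] = cur, _["converged"] = conv, _["t_stop"] = t_conv);
}

// Synchronous tissue update: at every step the per-cell environment is
// assembled from the *current* neighbour states (frozen across the RK4
// sub-stages of that step), then all cells advance one dt together.
// nbrs: ncell x 6 matrix of 1-based neighbour indices, 0 = missing (open
// boundary). agg: 0 = mean over existing neighbours, 1 = sum.
// globals: c(I_ext, sD_ext, sJ_ext).
// [[Rcpp::export]]
List cpp_simulate_tissue(NumericMatrix states, IntegerMatrix nbrs, int agg,
                         NumericVector globals, List cp,
                         double t_end, double dt, NumericVector snap_times) {
  Pars p = get_pars(cp);
  int n = states.nrow();
  if (nbrs.nrow() != n) stop("neighbour map does not match number of cells");
  int nsteps = (int) std::lround(t_end / dt);
  NumericMatrix cur = clone(states);
  NumericMatrix nxt(n, NSPEC);
  int nrec = snap_times.size();
  std::vector<int> rec_step(nrec);
  for (int r = 0; r < nrec; ++r)
    rec_step[r] = (int) std::lround(snap_times[r] / dt);
  List snaps(nrec);
  NumericVector snap_t(nrec);
  std::vector<double> y(NSPEC), e(NENV);
  const double Iext = globals[0], sDext = globals[1], sJext = globals[2];
  int next_rec = 0;
  while (next_rec < nrec && rec_step[next_rec] == 0) {
    snaps[next_rec] = clone(cur);
    snap_t[next_rec] = 0.0;
    ++next_rec;
  }
  std::vector<double> Nx(n), Dx(n), Jx(n);
  for (int s = 1; s <= nsteps; ++s) {
    // neighbour aggregation from the current synchronous state
    for (int i = 0; i < n; ++i) {
      double sN = 0, sD = 0, sJ = 0; int cnt = 0;
      for (int k = 0; k < 6; ++k) {
        int j = nbrs(i, k);
        if (j > 0) {
          sN += cur(j - 1, 0); sD += cur(j - 1, 1); sJ += cur(j - 1, 2);
          ++cnt;
        }
      }
      if (agg == 0 && cnt > 0) { sN /= cnt; sD /= cnt; sJ /= cnt; }
      Nx[i] = sN; Dx[i] = sD; Jx[i] = sJ;
    }
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < NSPEC; ++k) y[k] = cur(i, k);
      e[0] = Nx[i]; e[1] = Dx[i]; e[2] = Jx[i];
      e[3] = sDext; e[4] = sJext; e[5] = Iext;
      rk4_step(y.data(), e.data(), p, dt);
      check_finite(y.data(), s * dt, i);
      for (int k = 0; k < NSPEC; ++k) nxt(i, k) = y[k];
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < NSPEC; ++k) cur(i, k) = nxt(i, k);
    while (next_rec < nrec && rec_step[next_rec] == s) {
      snaps[next_rec] = clone(cur);
      snap_t[next_rec] = s * dt;
      ++next_rec;
    }
  }
  return List::create(_["final"] = cur, _["times"] = snap_t, _["snapshots"] = snaps);
}
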