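// Core numerical kernels: Calpha bead force field (harmonic bonds/angles,
// 12-10 Go native contacts, r^-12 excluded volume, sigmoidal cross-link
// restraints), BAOAB Langevin integration with epoch-switched restraints,
// steepest-descent relaxation, and the Debye scattering sum.
//
// Units: lengths in Angstrom, energies in kcal/mol, time in ps, mass in Da.
// 1 kcal/mol = 418.4 Da A^2 / ps^2 (KCAL2INT below).

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

static const double KCAL2INT = 418.4;  // kcal/mol -> Da A^2 ps^-2

struct Topo {
  int n;
  std::vector<int> bi, bj;          // bonds
  std::vector<double> b0;
  std::vector<int> ai, aj, ak;      // angles (j is the vertex)
  double ka, a0;
  std::vector<int> ci, cj;          // native contacts
  std::vector<double> c0;
  double kb, go_eps, eps_r, sig_r, rep_cut;
  double kxl, beta, l0;
  std::vector<int> ri, rj;          // all candidate restraints (bead pairs)
  std::unordered_set<long long> excl;  // pairs excluded from repulsion
  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * (long long)n + j;
  }
};

static Topo unpack(const List& topo) {
  Topo t;
  t.n = as<int>(topo["n"]);
  t.bi = as<std::vector<int>>(topo["bond_i"]);
  t.bj = as<std::vector<int>>(topo["bond_j"]);
  t.b0 = as<std::vector<double>>(topo["bond_b0"]);
  t.ai = as<std::vector<int>>(topo["ang_i"]);
  t.aj = as<std::vector<int>>(topo["ang_j"]);
  t.ak = as<std::vector<int>>(topo["ang_k"]);
  t.ci = as<std::vector<int>>(topo["con_i"]);
  t.cj = as<std::vector<int>>(topo["con_j"]);
  t.c0 = as<std::vector<double>>(topo["con_r0"]);
  t.ri = as<std::vector<int>>(topo["res_i"]);
  t.rj = as<std::vector<int>>(topo["res_j"]);
  t.kb = as<double>(topo["k_b"]);
  t.ka = as<double>(topo["k_a"]);
  t.a0 = as<double>(topo["a_0"]);
  t.go_eps = as<double>(topo["go_eps"]);
  t.eps_r = as<double>(topo["eps_r"]);
  t.sig_r = as<double>(topo["sig_r"]);
  t.rep_cut = as<double>(topo["rep_cutoff"]);
  t.kxl = as<double>(topo["k_xl"]);
  t.beta = as<double>(topo["beta"]);
  t.l0 = as<double>(topo["l_0"]);
  // exclusions: bonded pairs, angle-mates, native contacts
  for (size_t b = 0; b < t.bi.size(); ++b) t.excl.insert(t.key(t.bi[b], t.bj[b]));
  for (size_t a = 0; a < t.ai.size(); ++a) {
    t.excl.insert(t.key(t.ai[a], t.aj[a]));
    t.excl.insert(t.key(t.aj[a], t.ak[a]));
    t.excl.insert(t.key(t.ai[a], t.ak[a]));
  }
  for (size_t c = 0; c < t.ci.size(); ++c) t.excl.insert(t.key(t.ci[c], t.cj[c]));
  return t;
}

// energy and forces; active = 0-based indices into the restraint list
static double eval_forces(const Topo& t, const std::vector<double>& x,
                          const std::vector<int>& active,
                          std::vector<double>& f) {
  const int n = t.n;
  std::fill(f.begin(), f.end(), 0.0);
  double e = 0.0;

  // bonds: Kb (b - b0)^2
  for (size_t b = 0; b < t.bi.size(); ++b) {
    const int i = t.bi[b], j = t.bj[b];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double d = r - t.b0[b];
    e += t.kb * d * d;
    double fr = -2.0 * t.kb * d / r;  // dV/dr projected on unit vector
    f[3*i]   += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j]   -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
  }

  // angles: Ka (alpha - alpha0)^2, vertex j
  for (size_t a = 0; a < t.ai.size(); ++a) {
    const int i = t.ai[a], j = t.aj[a], k = t.ak[a];
    double ux = x[3*i] - x[3*j], uy = x[3*i+1] - x[3*j+1], uz = x[3*i+2] - x[3*j+2];
    double vx = x[3*k] - x[3*j], vy = x[3*k+1] - x[3*j+1], vz = x[3*k+2] - x[3*j+2];
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double nv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double c = (ux*vx + uy*vy + uz*vz) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;                 // collinear guard
    double th = std::acos(c);
    double dVdth = 2.0 * t.ka * (th - t.a0);
    // dc/d(a), dc/d(c-vec); dtheta/dx = -dc/dx / sin(theta)
    double dca_x = vx / (nu*nv) - c * ux / (nu*nu);
    double dca_y = vy / (nu*nv) - c * uy / (nu*nu);
    double dca_z = vz / (nu*nv) - c * uz / (nu*nu);
    double dck_x = ux / (nu*nv) - c * vx / (nv*nv);
    double dck_y = uy / (nu*nv) - c * vy / (nv*nv);
    double dck_z = uz / (nu*nv) - c * vz / (nv*nv);
    double pref = dVdth / s;   // force = -dV/dtheta * dtheta/dx = pref * dc/dx
    e += t.ka * (th - t.a0) * (th - t.a0);
    f[3*i]   += pref * dca_x; f[3*i+1] += pref * dca_y; f[3*i+2] += pref * dca_z;
    f[3*k]   += pref * dck_x; f[3*k+1] += pref * dck_y; f[3*k+2] += pref * dck_z;
    f[3*j]   -= pref * (dca_x + dck_x);
    f[3*j+1] -= pref * (dca_y + dck_y);
    f[3*j+2] -= pref * (dca_z + dck_z);
  }

  // native contacts: 12-10 form, minimum -go_eps at r = r0
  for (size_t cc = 0; cc < t.ci.size(); ++cc) {
    const int i = t.ci[cc], j = t.cj[cc];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double s2 = (t.c0[cc] / r) * (t.c0[cc] / r);
    double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
    e += t.go_eps * (5.0 * s12 - 6.0 * s10);
    double dVdr = 60.0 * t.go_eps * (s10 - s12) / r;
    double fr = -dVdr / r;
    f[3*i]   += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j]   -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
  }

  // excluded volume: eps_R (sig_R / r)^12 over non-excluded pairs within cutoff
  const double cut2 = t.rep_cut * t.rep_cut;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= cut2) continue;
      if (t.excl.count(t.key(i, j))) continue;
      double s2 = (t.sig_r * t.sig_r) / r2;
      double s12 = s2 * s2 * s2; s12 = s12 * s12;
      double v = t.eps_r * s12;
      e += v;
      double fr = 12.0 * v / r2;   // -dV/dr / r
      f[3*i]   += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
      f[3*j]   -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
    }
  }

  // active sigmoidal restraints: K_XL / (1 + exp(-beta (l - l0)))
  for (size_t p = 0; p < active.size(); ++p) {
    const int k = active[p];
    const int i = t.ri[k], j = t.rj[k];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double sg = 1.0 / (1.0 + std::exp(-t.beta * (r - t.l0)));
    e += t.kxl * sg;
    double dVdr = t.kxl * t.beta * sg * (1.0 - sg);
    double fr = -dVdr / std::max(r, 1e-12);
    f[3*i]   += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j]   -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
  }

  return e;
}

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix coords, List topo, IntegerVector active) {
  Topo t = unpack(topo);
  if (coords.nrow() != t.n) stop("coordinate count does not match bead count");
  std::vector<double> x(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i) {
    x[3*i] = coords(i, 0); x[3*i+1] = coords(i, 1); x[3*i+2] = coords(i, 2);
    if (!std::isfinite(x[3*i]) || !std::isfinite(x[3*i+1]) || !std::isfinite(x[3*i+2]))
      stop("non-finite coordinate for bead %d", i + 1);
  }
  std::vector<int> act(active.begin(), active.end());
  double e = eval_forces(t, x, act, f);
  NumericMatrix fm(t.n, 3);
  for (int i = 0; i < t.n; ++i) {
    fm(i, 0) = f[3*i]; fm(i, 1) = f[3*i+1]; fm(i, 2) = f[3*i+2];
  }
  return List::create(_["energy"] = e, _["forces"] = fm);
}

// BAOAB Langevin integrator.  epochs: matrix (n_epochs x N_c) of 1-based
// restraint indices (0 rows = unrestrained); epoch_steps: steps per epoch.
// Draws noise from R's RNG so a prior set.seed() fixes the trajectory.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix coords, NumericMatrix vel, List topo,
                      double dt, int nsteps, double friction, double mass,
                      double kT, int save_every, IntegerMatrix epochs,
                      int epoch_steps) {
  Topo t = unpack(topo);
  const int n = t.n;
  if (coords.nrow() != n || vel.nrow() != n) stop("coordinate/velocity shape mismatch");
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = coords(i, d); v[3*i+d] = vel(i, d); }

  const double inv_m = KCAL2INT / mass;            // force -> acceleration
  const double c1 = (friction > 0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = (friction > 0) ? std::sqrt((1.0 - c1 * c1) * kT * KCAL2INT / mass) : 0.0;
  const int n_epochs = epochs.nrow();
  const int nc = epochs.ncol();

  const int nsave = nsteps / save_every;
  NumericVector frames((R_xlen_t)nsave * n * 3);
  NumericVector epot(nsave), ekin(nsave), tsave(nsave);

  RNGScope scope;
  std::vector<int> active;
  int cur_epoch = -1;
  auto set_epoch = [&](int step) {
    if (n_epochs == 0) return;
    int ep = std::min(step / std::max(epoch_steps, 1), n_epochs - 1);
    if (ep != cur_epoch) {
      cur_epoch = ep;
      active.assign(nc, 0);
      for (int p = 0; p < nc; ++p) active[p] = epochs(ep, p) - 1;
    }
  };

  set_epoch(0);
  double e = eval_forces(t, x, active, f);
  int isave = 0;
  for (int step = 0; step < nsteps; ++step) {
    set_epoch(step);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] * inv_m;   // B
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];           // A
    if (friction > 0)                                                  // O
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];           // A
    e = eval_forces(t, x, active, f);                                  // B
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i] * inv_m;
    if (!std::isfinite(e) || e > 1e10) {
      double fmax = 0;
      for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
      stop("dynamics diverged at step %d (energy %g, max |force| %g); reduce the timestep",
           step + 1, e, fmax);
    }
    if ((step + 1) % save_every == 0) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) ke += v[3*i+d] * v[3*i+d];
      ke *= 0.5 * mass / KCAL2INT;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)isave * n * 3 + (R_xlen_t)i * 3 + d] = x[3*i+d];
      epot[isave] = e; ekin[isave] = ke; tsave[isave] = (step + 1) * dt;
      ++isave;
    }
  }

  NumericMatrix xm(n, 3), vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { xm(i, d) = x[3*i+d]; vm(i, d) = v[3*i+d]; }
  frames.attr("dim") = IntegerVector::create(3, n, nsave);
  return List::create(_["frames"] = frames, _["epot"] = epot, _["ekin"] = ekin,
                      _["time"] = tsave, _["coords"] = xm, _["vel"] = vm);
}

// steepest descent with displacement cap; used to relax grown flexible chains
// [[Rcpp::export]]
NumericMatrix relax_cpp(NumericMatrix coords, List topo, int nsteps, double max_disp) {
  Topo t = unpack(topo);
  const int n = t.n;
  std::vector<double> x(3 * n), f(3 * n);
  std::vector<int> active;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i, d);
  for (int it = 0; it < nsteps; ++it) {
    eval_forces(t, x, active, f);
    double fmax = 1e-12;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
    double alpha = std::min(1e-3, max_disp / fmax);
    for (int i = 0; i < 3 * n; ++i) x[i] += alpha * f[i];
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3*i+d];
  return out;
}

// Debye sum: I(q) = f^2 * sum_ij sinc(q r_ij); includes the i = j terms,
// so I(0) = (N f)^2.
// [[Rcpp::export]]
NumericVector debye_profile_cpp(NumericMatrix coords, NumericVector q, double f) {
  const int n = coords.nrow();
  const int nq = q.size();
  // pair distances once
  std::vector<double> rij;
  rij.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0) - coords(j,0);
      double dy = coords(i,1) - coords(j,1);
      double dz = coords(i,2) - coords(j,2);
      rij.push_back(std::sqrt(dx*dx + dy*dy + dz*dz));
    }
  NumericVector I(nq);
  const double f2 = f * f;
  for (int iq = 0; iq < nq; ++iq) {
    double qv = q[iq];
    double s = (double)n;           // self terms
    if (qv <= 0) {
      s += 2.0 * rij.size();
    } else {
      for (size_t p = 0; p < rij.size(); ++p) {
        double qr = qv * rij[p];
        s += 2.0 * ((qr < 1e-8) ? 1.0 : std::sin(qr) / qr);
      }
    }
    I[iq] = f2 * s;
  }
  return I;
}
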