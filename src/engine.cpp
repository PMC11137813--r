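// Langevin dynamics core for reduced heme-ligand complexes.
//
// Units: length Angstrom, energy kcal/mol, mass amu, time fs internally
// (durations cross the R boundary in ps, rates in Angstrom/ns).
// Acceleration conversion: 1 (kcal/mol/A)/amu = 4.184e-4 A/fs^2.
// Randomness comes from R's RNG so that set.seed() governs every stream.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double FCONV = 4.184e-4;       // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872041;      // kcal/mol/K

// CHARMM-style cubic-in-r^2 switching function and its r-derivative.
static inline void switch_fn(double r, double ron, double roff,
                             double &s, double &dsdr) {
  if (r <= ron) { s = 1.0; dsdr = 0.0; return; }
  if (r >= roff) { s = 0.0; dsdr = 0.0; return; }
  double r2 = r * r, ron2 = ron * ron, roff2 = roff * roff;
  double denom = std::pow(roff2 - ron2, 3);
  double a = roff2 - r2;
  s = a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / denom;
  dsdr = (2.0 * a * (-2.0 * r) * (roff2 + 2.0 * r2 - 3.0 * ron2) +
          a * a * (4.0 * r)) / denom;
}

// Switched 12-6 LJ (sigma form, eps stored as a magnitude).
static inline void lj_pair(double r, double eps, double sigma,
                           double ron, double roff,
                           double &u, double &fr) {
  // fr is -dU/dr (positive = repulsive along the pair axis)
  if (eps <= 0.0 || r >= roff) { u = 0.0; fr = 0.0; return; }
  double x6 = std::pow(sigma / r, 6);
  double u0 = 4.0 * eps * (x6 * x6 - x6);
  double du0 = (24.0 * eps / r) * (x6 - 2.0 * x6 * x6); // dU0/dr
  double s, dsdr;
  switch_fn(r, ron, roff, s, dsdr);
  u = u0 * s;
  fr = -(du0 * s + u0 * dsdr);
}

struct BiasRow {
  int kind;      // 0 harmonic, 1 moving harmonic, 2 upper wall, 3 lower wall
  int i, j;      // atom indices (0-based) of the distance CV
  double kappa, r0, rate_fs, ceiling;
};

// Bias energy/force on the CV value x at time t (fs).
static inline void bias_eval(const BiasRow &b, double x, double t,
                             double &u, double &fx) {
  // fx = -dU/dx
  switch (b.kind) {
  case 0: { double d = x - b.r0; u = 0.5 * b.kappa * d * d; fx = -b.kappa * d; break; }
  case 1: { double c = b.r0 + b.rate_fs * t; double d = x - c;
            u = 0.5 * b.kappa * d * d; fx = -b.kappa * d; break; }
  case 2: { if (x > b.ceiling) { double d = x - b.ceiling;
              u = 0.5 * b.kappa * d * d; fx = -b.kappa * d; }
            else { u = 0.0; fx = 0.0; } break; }
  default: { if (x < b.ceiling) { double d = x - b.ceiling;
              u = 0.5 * b.kappa * d * d; fx = -b.kappa * d; }
            else { u = 0.0; fx = 0.0; } break; }
  }
}

struct MetadState {
  bool active = false;
  int ci1, cj1, ci2, cj2;     // CV atom pairs; ci2 < 0 => 1 CV
  double h0, sig, gamma, kT;
  int stride;
  double xmin, dx;
  int nbin;
  std::vector<double> V, dV1, dV2; // grids (nbin x nbin, row-major; 1D uses first row)
  std::vector<double> log_t, log_c1, log_c2, log_h;
  bool two_d() const { return ci2 >= 0; }
  int idx(int a, int b) const { return a * nbin + b; }
  void value_grad(double s1, double s2, double &v, double &g1, double &g2) const {
    // bilinear interpolation, clamped to the grid
    double u = (s1 - xmin) / dx, w = (s2 - xmin) / dx;
    if (!two_d()) w = 0.0;
    u = std::min(std::max(u, 0.0), (double)(nbin - 1) - 1e-9);
    w = std::min(std::max(w, 0.0), (double)(nbin - 1) - 1e-9);
    int a = (int)u, b = (int)w;
    double fu = u - a, fw = w - b;
    int a1 = std::min(a + 1, nbin - 1), b1 = std::min(b + 1, nbin - 1);
    auto bl = [&](const std::vector<double> &G) {
      return G[idx(a, b)] * (1 - fu) * (1 - fw) + G[idx(a1, b)] * fu * (1 - fw) +
             G[idx(a, b1)] * (1 - fu) * fw + G[idx(a1, b1)] * fu * fw;
    };
    v = bl(V); g1 = bl(dV1); g2 = two_d() ? bl(dV2) : 0.0;
  }
  void deposit(double s1, double s2, double t_ps) {
    double v, g1, g2;
    value_grad(s1, s2, v, g1, g2);
    double h = h0 * std::exp(-v / ((gamma - 1.0) * kT));
    int half = (int)std::ceil(5.0 * sig / dx);
    int a0 = std::max(0, (int)((s1 - xmin) / dx) - half);
    int a1 = std::min(nbin - 1, (int)((s1 - xmin) / dx) + half);
    if (two_d()) {
      int b0 = std::max(0, (int)((s2 - xmin) / dx) - half);
      int b1 = std::min(nbin - 1, (int)((s2 - xmin) / dx) + half);
      for (int a = a0; a <= a1; ++a) {
        double x1 = xmin + a * dx, d1 = x1 - s1;
        double e1 = std::exp(-0.5 * d1 * d1 / (sig * sig));
        for (int b = b0; b <= b1; ++b) {
          double x2 = xmin + b * dx, d2 = x2 - s2;
          double g = h * e1 * std::exp(-0.5 * d2 * d2 / (sig * sig));
          V[idx(a, b)] += g;
          dV1[idx(a, b)] += g * (-d1 / (sig * sig));
          dV2[idx(a, b)] += g * (-d2 / (sig * sig));
        }
      }
    } else {
      for (int a = a0; a <= a1; ++a) {
        double x1 = xmin + a * dx, d1 = x1 - s1;
        double g = h * std::exp(-0.5 * d1 * d1 / (sig * sig));
        V[idx(a, 0)] += g;
        dV1[idx(a, 0)] += g * (-d1 / (sig * sig));
      }
    }
    log_t.push_back(t_ps); log_c1.push_back(s1);
    log_c2.push_back(two_d() ? s2 : NA_REAL); log_h.push_back(h);
  }
};

static inline double dist3(const std::vector<double> &x, int i, int j,
                           double *unit = nullptr) {
  double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
         dz = x[3 * j + 2] - x[3 * i + 2];
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (unit) { unit[0] = dx / r; unit[1] = dy / r; unit[2] = dz / r; }
  return r;
}

// [[Rcpp::export]]
double pair_energy_cpp(NumericMatrix pos, NumericMatrix pairs,
                       double r_on, double r_off) {
  double e = 0.0;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = (int)pairs(k, 0) - 1, j = (int)pairs(k, 1) - 1;
    double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1),
           dz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double u, fr;
    lj_pair(r, pairs(k, 2), pairs(k, 3), r_on, r_off, u, fr);
    e += u;
  }
  return e;
}

// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                IntegerVector mobile, NumericMatrix pairs,
                NumericMatrix constraints, NumericMatrix biases,
                double nsteps_d, double dt, double temperature,
                double gamma_ps, double r_on, double r_off,
                int sample_stride, bool record_positions,
                Nullable<List> metad_spec) {
  const long long nsteps = (long long)nsteps_d;
  const int n = pos0.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), m(n), minv(n);
  std::vector<int> mob(n);
  for (int i = 0; i < n; ++i) {
    m[i] = mass[i];
    mob[i] = mobile[i];
    minv[i] = mob[i] ? 1.0 / m[i] : 0.0;
    for (int d = 0; d < 3; ++d) { x[3*i+d] = pos0(i, d); v[3*i+d] = mob[i] ? vel0(i, d) : 0.0; }
  }
  const int npair = pairs.nrow(), ncon = constraints.nrow(), nbias = biases.nrow();
  std::vector<BiasRow> bs(nbias);
  for (int k = 0; k < nbias; ++k) {
    bs[k].kind = (int)biases(k, 0);
    bs[k].i = (int)biases(k, 1) - 1; bs[k].j = (int)biases(k, 2) - 1;
    bs[k].kappa = biases(k, 3); bs[k].r0 = biases(k, 4);
    bs[k].rate_fs = biases(k, 5) * 1e-6; // A/ns -> A/fs
    bs[k].ceiling = biases(k, 6);
  }

  MetadState md;
  if (metad_spec.isNotNull()) {
    List ms(metad_spec);
    IntegerMatrix cv = ms["cv"];
    md.active = true;
    md.ci1 = cv(0, 0) - 1; md.cj1 = cv(0, 1) - 1;
    if (cv.nrow() > 1) { md.ci2 = cv(1, 0) - 1; md.cj2 = cv(1, 1) - 1; }
    else { md.ci2 = -1; md.cj2 = -1; }
    md.h0 = as<double>(ms["height"]);
    md.sig = as<double>(ms["sigma"]);
    md.gamma = as<double>(ms["bias_factor"]);
    md.kT = KB * temperature;
    md.stride = as<int>(ms["stride_steps"]);
    md.xmin = as<double>(ms["grid_min"]);
    double xmax = as<double>(ms["grid_max"]);
    md.nbin = as<int>(ms["grid_n"]);
    md.dx = (xmax - md.xmin) / (md.nbin - 1);
    size_t g = (size_t)md.nbin * md.nbin;
    md.V.assign(g, 0.0); md.dV1.assign(g, 0.0); md.dV2.assign(g, 0.0);
  }

  // degrees of freedom for the kinetic temperature (mobile sites only)
  int nmob = 0;
  for (int i = 0; i < n; ++i) nmob += mob[i];
  int ncon_mob = 0;
  for (int k = 0; k < ncon; ++k) {
    int i = (int)constraints(k, 0) - 1, j = (int)constraints(k, 1) - 1;
    if (mob[i] || mob[j]) ++ncon_mob;
  }
  const double dof = std::max(1, 3 * nmob - ncon_mob);

  const double c1 = std::exp(-gamma_ps * 1e-3 * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  // flatten the pair table for the inner loop
  std::vector<int> p_i(npair), p_j(npair);
  std::vector<double> p_eps(npair), p_sig2(npair);
  for (int k = 0; k < npair; ++k) {
    p_i[k] = (int)pairs(k, 0) - 1; p_j[k] = (int)pairs(k, 1) - 1;
    p_eps[k] = pairs(k, 2); p_sig2[k] = pairs(k, 3) * pairs(k, 3);
  }
  const double roff2 = r_off * r_off, ron2 = r_on * r_on;

  auto compute_forces = [&](double t) {
    std::fill(f.begin(), f.end(), 0.0);
    for (int k = 0; k < npair; ++k) {
      const int i = p_i[k], j = p_j[k];
      const double dxv = x[3*j] - x[3*i], dyv = x[3*j+1] - x[3*i+1],
                   dzv = x[3*j+2] - x[3*i+2];
      const double r2 = dxv*dxv + dyv*dyv + dzv*dzv;
      if (r2 >= roff2 || r2 < 1e-18 || p_eps[k] <= 0.0) continue;
      const double x2 = p_sig2[k] / r2;
      const double x6 = x2 * x2 * x2;
      // -dU/dr / r (so force vector = coef * dvec)
      double coef = (24.0 * p_eps[k] / r2) * (2.0 * x6 * x6 - x6);
      if (r2 > ron2) {
        const double r = std::sqrt(r2);
        double s, dsdr;
        switch_fn(r, r_on, r_off, s, dsdr);
        const double u0 = 4.0 * p_eps[k] * (x6 * x6 - x6);
        coef = coef * s - u0 * dsdr / r;
      }
      f[3*j]   += coef * dxv; f[3*j+1] += coef * dyv; f[3*j+2] += coef * dzv;
      f[3*i]   -= coef * dxv; f[3*i+1] -= coef * dyv; f[3*i+2] -= coef * dzv;
    }
    for (int k = 0; k < nbias; ++k) {
      double u[3];
      double r = dist3(x, bs[k].i, bs[k].j, u);
      double ub, fb;
      bias_eval(bs[k], r, t, ub, fb);
      for (int d = 0; d < 3; ++d) { f[3*bs[k].j+d] += fb * u[d]; f[3*bs[k].i+d] -= fb * u[d]; }
    }
    if (md.active) {
      double u1[3], u2[3];
      double s1 = dist3(x, md.ci1, md.cj1, u1);
      double s2 = md.two_d() ? dist3(x, md.ci2, md.cj2, u2) : 0.0;
      double v_, g1, g2;
      md.value_grad(s1, s2, v_, g1, g2);
      for (int d = 0; d < 3; ++d) {
        f[3*md.cj1+d] -= g1 * u1[d]; f[3*md.ci1+d] += g1 * u1[d];
        if (md.two_d()) { f[3*md.cj2+d] -= g2 * u2[d]; f[3*md.ci2+d] += g2 * u2[d]; }
      }
    }
  };

  auto shake = [&](const std::vector<double> &xref) {
    for (int it = 0; it < 100; ++it) {
      double maxdev = 0.0;
      for (int k = 0; k < ncon; ++k) {
        int i = (int)constraints(k, 0) - 1, j = (int)constraints(k, 1) - 1;
        double L = constraints(k, 2);
        double dxv = x[3*j] - x[3*i], dyv = x[3*j+1] - x[3*i+1], dzv = x[3*j+2] - x[3*i+2];
        double r2 = dxv*dxv + dyv*dyv + dzv*dzv;
        double diff = r2 - L * L;
        maxdev = std::max(maxdev, std::fabs(diff));
        if (std::fabs(diff) < 1e-12) continue;
        double rxr = xref[3*j] - xref[3*i], ryr = xref[3*j+1] - xref[3*i+1],
               rzr = xref[3*j+2] - xref[3*i+2];
        double dot = dxv * rxr + dyv * ryr + dzv * rzr;
        double w = minv[i] + minv[j];
        if (w <= 0.0 || std::fabs(dot) < 1e-12) continue;
        double g = diff / (2.0 * w * dot);
        x[3*i]   += g * minv[i] * rxr; x[3*i+1] += g * minv[i] * ryr; x[3*i+2] += g * minv[i] * rzr;
        x[3*j]   -= g * minv[j] * rxr; x[3*j+1] -= g * minv[j] * ryr; x[3*j+2] -= g * minv[j] * rzr;
      }
      if (maxdev < 1e-12) break;
    }
  };
  auto rattle_v = [&]() {
    for (int k = 0; k < ncon; ++k) {
      int i = (int)constraints(k, 0) - 1, j = (int)constraints(k, 1) - 1;
      double dxv = x[3*j] - x[3*i], dyv = x[3*j+1] - x[3*i+1], dzv = x[3*j+2] - x[3*i+2];
      double r2 = dxv*dxv + dyv*dyv + dzv*dzv;
      double w = minv[i] + minv[j];
      if (w <= 0.0) continue;
      double rv = dxv * (v[3*j]-v[3*i]) + dyv * (v[3*j+1]-v[3*i+1]) + dzv * (v[3*j+2]-v[3*i+2]);
      double lam = rv / (w * r2);
      v[3*i]   += lam * minv[i] * dxv; v[3*i+1] += lam * minv[i] * dyv; v[3*i+2] += lam * minv[i] * dzv;
      v[3*j]   -= lam * minv[j] * dxv; v[3*j+1] -= lam * minv[j] * dyv; v[3*j+2] -= lam * minv[j] * dzv;
    }
  };

  const long long nsamp = nsteps / sample_stride;
  NumericVector s_t(nsamp), s_temp(nsamp);
  NumericMatrix s_cv(nsamp, std::max(1, nbias));
  NumericMatrix s_bforce(nsamp, std::max(1, nbias));
  NumericMatrix s_pos(record_positions ? nsamp : 0, record_positions ? 3 * n : 0);
  NumericMatrix s_mcv(md.active ? nsamp : 0, md.active ? 2 : 0);

  RNGScope rng;
  compute_forces(0.0);
  long long isamp = 0;
  long long diverged_at = -1;
  std::vector<double> xref(3 * n);

  for (long long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    // BAOAB with SHAKE/RATTLE on rigid bonds
    for (int i = 0; i < n; ++i) if (mob[i])
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * f[3*i+d] * FCONV * minv[i] * m[i] * minv[i];
    rattle_v();
    xref = x;
    for (int i = 0; i < n; ++i) if (mob[i])
      for (int d = 0; d < 3; ++d) x[3*i+d] += 0.5 * dt * v[3*i+d];
    if (temperature > 0.0 || gamma_ps > 0.0) {
      for (int i = 0; i < n; ++i) if (mob[i]) {
        double sd = std::sqrt(KB * temperature * FCONV / m[i]);
        for (int d = 0; d < 3; ++d)
          v[3*i+d] = c1 * v[3*i+d] + c2 * sd * norm_rand();
      }
      rattle_v();
    }
    for (int i = 0; i < n; ++i) if (mob[i])
      for (int d = 0; d < 3; ++d) x[3*i+d] += 0.5 * dt * v[3*i+d];
    if (ncon) { shake(xref); rattle_v(); }
    compute_forces(t + dt);
    for (int i = 0; i < n; ++i) if (mob[i])
      for (int d = 0; d < 3; ++d) v[3*i+d] += 0.5 * dt * f[3*i+d] * FCONV * minv[i] * m[i] * minv[i];
    rattle_v();

    if (md.active && ((step + 1) % md.stride == 0)) {
      double s1 = dist3(x, md.ci1, md.cj1);
      double s2 = md.two_d() ? dist3(x, md.ci2, md.cj2) : 0.0;
      md.deposit(s1, s2, (t + dt) * 1e-3);
    }

    if ((step + 1) % sample_stride == 0 && isamp < nsamp) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) if (mob[i])
        for (int d = 0; d < 3; ++d) ke += 0.5 * m[i] * v[3*i+d] * v[3*i+d] / FCONV;
      s_t[isamp] = (t + dt) * 1e-3; // ps
      s_temp[isamp] = 2.0 * ke / (dof * KB);
      for (int k = 0; k < nbias; ++k) {
        double r = dist3(x, bs[k].i, bs[k].j);
        s_cv(isamp, k) = r;
        double ref = bs[k].kind == 1 ? bs[k].r0 + bs[k].rate_fs * (t + dt) : bs[k].r0;
        s_bforce(isamp, k) = bs[k].kappa * (ref - r); // spring force along the CV
      }
      if (md.active) {
        s_mcv(isamp, 0) = dist3(x, md.ci1, md.cj1);
        s_mcv(isamp, 1) = md.two_d() ? dist3(x, md.ci2, md.cj2) : NA_REAL;
      }
      if (record_positions)
        for (int i = 0; i < 3 * n; ++i) s_pos(isamp, i) = x[i];
      bool bad = false;
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e5) bad = true;
      if (bad) { diverged_at = step + 1; ++isamp; break; }
      ++isamp;
    }
  }

  NumericMatrix posf(n, 3), velf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { posf(i, d) = x[3*i+d]; velf(i, d) = v[3*i+d]; }

  List hills = R_NilValue;
  List grids = R_NilValue;
  if (md.active) {
    hills = List::create(_["t_ps"] = wrap(md.log_t), _["center1"] = wrap(md.log_c1),
                         _["center2"] = wrap(md.log_c2), _["height"] = wrap(md.log_h));
    grids = List::create(_["V"] = wrap(md.V), _["nbin"] = md.nbin,
                         _["grid_min"] = md.xmin, _["dx"] = md.dx,
                         _["two_d"] = md.two_d());
  }
  return List::create(
    _["pos"] = posf, _["vel"] = velf, _["t_ps"] = s_t, _["temperature"] = s_temp,
    _["cv"] = s_cv, _["bias_force"] = s_bforce, _["metad_cv"] = s_mcv,
    _["positions"] = s_pos, _["hills"] = hills, _["bias_grid"] = grids,
    _["diverged_at"] = (double)diverged_at, _["n_samples"] = (double)isamp);
}

// One-dimensional Langevin particle on an analytic landscape; validation
// harness for the thermostat and the well-tempered bias machinery.
// pot_kind: 0 flat, 1 harmonic 0.5*k*(x-x0)^2 (par = k, x0),
//           2 quartic double well h*((x/a)^2-1)^2 (par = h, a)
// [[Rcpp::export]]
List run_cv1d_cpp(double x0, double v0, double mass, int pot_kind,
                  NumericVector pot_par, double nsteps_d, double dt,
                  double temperature, double gamma_ps, int sample_stride,
                  double wall_lo, double wall_hi, double wall_kappa,
                  Nullable<List> metad_spec) {
  const long long nsteps = (long long)nsteps_d;
  double x = x0, v = v0;
  const double c1 = std::exp(-gamma_ps * 1e-3 * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double sd = std::sqrt(KB * temperature * FCONV / mass);

  MetadState md;
  if (metad_spec.isNotNull()) {
    List ms(metad_spec);
    md.active = true;
    md.ci1 = 0; md.cj1 = 0; md.ci2 = -1; md.cj2 = -1;
    md.h0 = as<double>(ms["height"]);
    md.sig = as<double>(ms["sigma"]);
    md.gamma = as<double>(ms["bias_factor"]);
    md.kT = KB * temperature;
    md.stride = as<int>(ms["stride_steps"]);
    md.xmin = as<double>(ms["grid_min"]);
    double xmax = as<double>(ms["grid_max"]);
    md.nbin = as<int>(ms["grid_n"]);
    md.dx = (xmax - md.xmin) / (md.nbin - 1);
    md.V.assign((size_t)md.nbin * md.nbin, 0.0);
    md.dV1.assign((size_t)md.nbin * md.nbin, 0.0);
    md.dV2.assign((size_t)md.nbin * md.nbin, 0.0);
  }

  auto force = [&](double xx) {
    double fr = 0.0;
    if (pot_kind == 1) fr = -pot_par[0] * (xx - pot_par[1]);
    else if (pot_kind == 2) {
      double a = pot_par[1], y = xx / a;
      fr = -pot_par[0] * 2.0 * (y * y - 1.0) * 2.0 * y / a;
    }
    if (wall_kappa > 0.0) {
      if (xx > wall_hi) fr += -wall_kappa * (xx - wall_hi);
      if (xx < wall_lo) fr += -wall_kappa * (xx - wall_lo);
    }
    if (md.active) {
      double vv, g1, g2;
      md.value_grad(xx, 0.0, vv, g1, g2);
      fr += -g1;
    }
    return fr;
  };

  const long long nsamp = nsteps / sample_stride;
  NumericVector s_t(nsamp), s_x(nsamp), s_temp(nsamp);
  RNGScope rng;
  double f = force(x);
  long long isamp = 0;
  for (long long step = 0; step < nsteps; ++step) {
    v += 0.5 * dt * f * FCONV / mass;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * sd * norm_rand();
    x += 0.5 * dt * v;
    f = force(x);
    v += 0.5 * dt * f * FCONV / mass;
    if (md.active && ((step + 1) % md.stride == 0))
      md.deposit(x, 0.0, (step + 1) * dt * 1e-3);
    if ((step + 1) % sample_stride == 0 && isamp < nsamp) {
      s_t[isamp] = (step + 1) * dt * 1e-3;
      s_x[isamp] = x;
      s_temp[isamp] = mass * v * v / (FCONV * KB);
      ++isamp;
    }
  }
  List hills = R_NilValue, grids = R_NilValue;
  if (md.active) {
    hills = List::create(_["t_ps"] = wrap(md.log_t), _["center1"] = wrap(md.log_c1),
                         _["center2"] = wrap(md.log_c2), _["height"] = wrap(md.log_h));
    grids = List::create(_["V"] = wrap(md.V), _["nbin"] = md.nbin,
                         _["grid_min"] = md.xmin, _["dx"] = md.dx,
                         _["two_d"] = false);
  }
  return List::create(_["t_ps"] = s_t, _["x"] = s_x, _["temperature"] = s_temp,
                      _["x_final"] = x, _["v_final"] = v,
                      _["hills"] = hills, _["bias_grid"] = grids);
}
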