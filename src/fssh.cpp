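// Fewest-switches surface hopping on analytic model Hamiltonians.
// Units: energy eV, length A, mass amu, time fs.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double HBAR_EVFS = 0.6582119569;     // hbar in eV fs
static const double AMU_A2FS2_TO_EV = 103.642697; // 1 amu (A/fs)^2 in eV

// ---- model form registry -------------------------------------------------
// form codes: 1 avoided_crossing, 2 harmonic, 3 coupled_harmonics,
//             4 carotenoid, 0 custom (R callbacks; handled R-side)

static mat diab_avoided_crossing(const vec& p, const vec& x) {
  // Tully-type single avoided crossing: p = (A, B, C, D)
  double A = p(0), B = p(1), C = p(2), D = p(3);
  double q = x(0);
  double v11 = (q >= 0.0) ? A * (1.0 - std::exp(-B * q))
                          : -A * (1.0 - std::exp(B * q));
  double v12 = C * std::exp(-D * q * q);
  mat V(2, 2);
  V(0, 0) = v11; V(1, 1) = -v11;
  V(0, 1) = v12; V(1, 0) = v12;
  return V;
}

static cube grad_avoided_crossing(const vec& p, const vec& x) {
  double A = p(0), B = p(1), C = p(2), D = p(3);
  double q = x(0);
  double dv11 = A * B * std::exp(-B * std::abs(q));
  double dv12 = -2.0 * D * q * C * std::exp(-D * q * q);
  cube G(2, 2, 1, fill::zeros);
  G(0, 0, 0) = dv11; G(1, 1, 0) = -dv11;
  G(0, 1, 0) = dv12; G(1, 0, 0) = dv12;
  return G;
}

static mat diab_harmonic(const vec& p, const vec& x) {
  // single surface: p = (k_1..k_n, x0_1..x0_n)
  int n = x.n_elem;
  double v = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = x(i) - p(n + i);
    v += 0.5 * p(i) * d * d;
  }
  mat V(1, 1); V(0, 0) = v;
  return V;
}

static cube grad_harmonic(const vec& p, const vec& x) {
  int n = x.n_elem;
  cube G(1, 1, n);
  for (int i = 0; i < n; ++i) G(0, 0, i) = p(i) * (x(i) - p(n + i));
  return G;
}

static mat diab_coupled_harmonics(const vec& p, const vec& x, int ns) {
  // ns states, 1 dof: p = (k_1..k_ns, a_1..a_ns, e_1..e_ns, c_upper_tri)
  double q = x(0);
  mat V(ns, ns, fill::zeros);
  for (int i = 0; i < ns; ++i) {
    double d = q - p(ns + i);
    V(i, i) = 0.5 * p(i) * d * d + p(2 * ns + i);
  }
  int idx = 3 * ns;
  for (int i = 0; i < ns; ++i)
    for (int j = i + 1; j < ns; ++j) {
      V(i, j) = p(idx); V(j, i) = p(idx); ++idx;
    }
  return V;
}

static cube grad_coupled_harmonics(const vec& p, const vec& x, int ns) {
  double q = x(0);
  cube G(ns, ns, 1, fill::zeros);
  for (int i = 0; i < ns; ++i) G(i, i, 0) = p(i) * (q - p(ns + i));
  return G;
}

// carotenoid surrogate: 3 states (S0,S1,S2), 2 dof (BLA b in A, torsion th rad)
// p = (k0, b0, k1, e1, k2, b2, e2, kth0, kth1, kth2, c01, wb, cth, c12, c02)
static mat diab_carotenoid(const vec& p, const vec& x) {
  double b = x(0), th = x(1);
  double tors = 0.5 * (1.0 - std::cos(2.0 * th)); // 0 at planar, 1 at 90 deg
  double s2 = std::sin(th) * std::sin(th);
  mat V(3, 3, fill::zeros);
  V(0, 0) = 0.5 * p(0) * (b - p(1)) * (b - p(1)) + p(7) * tors;
  V(1, 1) = p(3) + 0.5 * p(2) * b * b + p(8) * tors;
  V(2, 2) = p(6) + 0.5 * p(4) * (b - p(5)) * (b - p(5)) + p(9) * tors;
  double sig = 1.0 / (1.0 + std::exp(b / p(11))); // -> 1 as b goes negative
  V(0, 1) = V(1, 0) = p(10) * sig * (1.0 + p(12) * s2);
  V(1, 2) = V(2, 1) = p(13);
  V(0, 2) = V(2, 0) = p(14);
  return V;
}

static cube grad_carotenoid(const vec& p, const vec& x) {
  double b = x(0), th = x(1);
  double s2 = std::sin(th) * std::sin(th);
  double dtors = std::sin(2.0 * th); // d/dth of 0.5(1-cos2th)
  double ds2 = 2.0 * std::sin(th) * std::cos(th);
  cube G(3, 3, 2, fill::zeros);
  G(0, 0, 0) = p(0) * (b - p(1));
  G(1, 1, 0) = p(2) * b;
  G(2, 2, 0) = p(4) * (b - p(5));
  G(0, 0, 1) = p(7) * dtors;
  G(1, 1, 1) = p(8) * dtors;
  G(2, 2, 1) = p(9) * dtors;
  double e = std::exp(b / p(11));
  double sig = 1.0 / (1.0 + e);
  double dsig = -e / ((1.0 + e) * (1.0 + e)) / p(11);
  G(0, 1, 0) = G(1, 0, 0) = p(10) * dsig * (1.0 + p(12) * s2);
  G(0, 1, 1) = G(1, 0, 1) = p(10) * sig * p(12) * ds2;
  return G;
}

static mat diabatic_eval(int form, const vec& p, const vec& x, int ns) {
  switch (form) {
    case 1: return diab_avoided_crossing(p, x);
    case 2: return diab_harmonic(p, x);
    case 3: return diab_coupled_harmonics(p, x, ns);
    case 4: return diab_carotenoid(p, x);
  }
  Rcpp::stop("unknown model form code");
}

static cube diabatic_grad(int form, const vec& p, const vec& x, int ns) {
  switch (form) {
    case 1: return grad_avoided_crossing(p, x);
    case 2: return grad_harmonic(p, x);
    case 3: return grad_coupled_harmonics(p, x, ns);
    case 4: return grad_carotenoid(p, x);
  }
  Rcpp::stop("unknown model form code");
}

// [[Rcpp::export]]
arma::mat cpp_diabatic(int form, const arma::vec& params, const arma::vec& coords,
                       int n_states) {
  return diabatic_eval(form, params, coords, n_states);
}

// [[Rcpp::export]]
arma::cube cpp_diabatic_grad(int form, const arma::vec& params,
                             const arma::vec& coords, int n_states) {
  return diabatic_grad(form, params, coords, n_states);
}

// deterministic eigenvector phase: largest-|component| entry made positive
static void fix_phase(mat& U) {
  for (uword k = 0; k < U.n_cols; ++k) {
    uword imax = index_max(abs(U.col(k)));
    if (U(imax, k) < 0) U.col(k) *= -1.0;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_adiabatic(int form, const arma::vec& params, const arma::vec& coords,
                         int n_states) {
  mat V = diabatic_eval(form, params, coords, n_states);
  vec E; mat U;
  eig_sym(E, U, V);
  fix_phase(U);
  return Rcpp::List::create(Rcpp::Named("energies") = E,
                            Rcpp::Named("vectors") = U);
}

// propagator for one electronic substep: exp(-i H dt / hbar), H real symmetric
static cx_mat expm_herm(const mat& H, double dt) {
  if (H.n_rows == 2) {
    // Pauli decomposition closed form for 2x2
    double d0 = 0.5 * (H(0, 0) + H(1, 1));
    double hz = 0.5 * (H(0, 0) - H(1, 1));
    double hx = H(0, 1);
    double w = std::sqrt(hz * hz + hx * hx);
    double phi = dt / HBAR_EVFS;
    cx_double g = std::exp(cx_double(0.0, -d0 * phi));
    double cw = std::cos(w * phi);
    double sw = (w > 1e-300) ? std::sin(w * phi) / w : phi;
    cx_mat P(2, 2);
    P(0, 0) = g * cx_double(cw, -sw * hz);
    P(1, 1) = g * cx_double(cw, sw * hz);
    P(0, 1) = g * cx_double(0.0, -sw * hx);
    P(1, 0) = P(0, 1);
    return P;
  }
  vec w; mat Q;
  eig_sym(w, Q, H);
  cx_vec ph = exp(cx_double(0.0, -dt / HBAR_EVFS) * conv_to<cx_vec>::from(w));
  return conv_to<cx_mat>::from(Q) * diagmat(ph) * conv_to<cx_mat>::from(Q.t());
}

// Lowdin orthonormalization of the overlap matrix
static mat lowdin(const mat& S) {
  mat U, V; vec s;
  svd(U, s, V, S);
  return U * V.t();
}

// ---- main propagation loop ----------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_propagate(int form, const arma::vec& params, int n_states,
                         const arma::vec& masses,
                         const arma::vec& coords0, const arma::vec& vel0,
                         int state0, const arma::vec& coeffs0_re,
                         const arma::vec& coeffs0_im,
                         const arma::mat& dipole_diab,
                         double dt, int substeps, int nsteps,
                         int deco_scheme,           // 0 none, 1 overlap, 2 energy
                         double deco_width,         // amu^1/2 A (overlap)
                         double deco_threshold,     // overlap collapse threshold
                         double deco_const,         // eV (energy-based C)
                         int frustrated_policy,     // 0 ignore, 1 reverse
                         double energy_tol,         // eV drift tolerance per ps
                         int seed,
                         int record_stride,
                         double exit_abs_coord) {   // <=0: disabled
  int nd = coords0.n_elem;
  bool have_dip = dipole_diab.n_rows == (uword)n_states;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  vec x = coords0, v = vel0;
  int active = state0;
  cx_vec c = cx_vec(coeffs0_re, coeffs0_im);

  mat V = diabatic_eval(form, params, x, n_states);
  vec E; mat U;
  eig_sym(E, U, V);
  fix_phase(U);
  cube G = diabatic_grad(form, params, x, n_states);

  auto adiab_grad = [&](const cube& Gd, const mat& Uad, int k) {
    vec g(nd);
    for (int i = 0; i < nd; ++i)
      g(i) = as_scalar(Uad.col(k).t() * Gd.slice(i) * Uad.col(k));
    return g;
  };
  auto kinetic = [&](const vec& vv) {
    return 0.5 * AMU_A2FS2_TO_EV * accu(masses % vv % vv);
  };

  vec g_act = adiab_grad(G, U, active);
  double etot_ref = kinetic(v) + E(active);

  // decoherence auxiliaries (overlap scheme)
  mat aux_dx(nd, n_states, fill::zeros), aux_dp(nd, n_states, fill::zeros);

  int nrec = nsteps / record_stride + 1;
  mat rec_x(nrec, nd), rec_v(nrec, nd), rec_E(nrec, n_states);
  cx_mat rec_c(nrec, n_states);
  mat rec_dip(nrec, n_states, fill::zeros);
  ivec rec_state(nrec);
  vec rec_t(nrec);
  int irec = 0;

  auto record = [&](double t) {
    rec_t(irec) = t;
    rec_x.row(irec) = x.t();
    rec_v.row(irec) = v.t();
    rec_E.row(irec) = E.t();
    rec_c.row(irec) = c.t();
    rec_state(irec) = active;
    if (have_dip) {
      mat mu = U.t() * dipole_diab * U;
      rec_dip.row(irec) = mu.row(active);
    }
    ++irec;
  };
  record(0.0);

  std::vector<double> hop_t, hop_gap;
  std::vector<int> hop_from, hop_to;
  std::vector<std::vector<double>> hop_x;
  bool exited = false;
  int step_done = 0;

  for (int step = 1; step <= nsteps; ++step) {
    // velocity Verlet on the active surface
    vec a = -g_act / (masses * AMU_A2FS2_TO_EV);
    vec x_new = x + v * dt + 0.5 * a * dt * dt;

    mat V_new = diabatic_eval(form, params, x_new, n_states);
    if (!V_new.is_finite())
      Rcpp::stop("non-finite potential at step %d", step);
    vec E_new; mat U_new;
    eig_sym(E_new, U_new, V_new);
    fix_phase(U_new);
    // continuity phase correction relative to previous eigenvectors
    for (int k = 0; k < n_states; ++k)
      if (dot(U.col(k), U_new.col(k)) < 0) U_new.col(k) *= -1.0;

    cube G_new = diabatic_grad(form, params, x_new, n_states);
    vec g_new = adiab_grad(G_new, U_new, active);
    vec a_new = -g_new / (masses * AMU_A2FS2_TO_EV);
    vec v_new = v + 0.5 * (a + a_new) * dt;

    // locally diabatic electronic propagation over the nuclear step
    mat S = U.t() * U_new;
    mat T = lowdin(S);
    mat H0 = diagmat(E);
    mat H1 = T * diagmat(E_new) * T.t();
    cx_mat P(n_states, n_states, fill::eye);
    double dtau = dt / substeps;
    for (int s = 0; s < substeps; ++s) {
      double frac = (s + 0.5) / substeps;
      mat H = (1.0 - frac) * H0 + frac * H1;
      P = expm_herm(H, dtau) * P;
    }
    P = conv_to<cx_mat>::from(T.t()) * P; // adiabatic(t) -> adiabatic(t+dt)
    cx_vec c_new = P * c;

    // net population flux and fewest-switches hop probabilities
    vec pop_old = square(abs(c));
    mat M(n_states, n_states);
    for (int j = 0; j < n_states; ++j)
      for (int k = 0; k < n_states; ++k)
        M(j, k) = std::real(std::conj(c_new(k)) * P(k, j) * c(j));
    mat N = M - M.t();
    vec g(n_states, fill::zeros);
    if (pop_old(active) > 1e-12) {
      for (int k = 0; k < n_states; ++k)
        if (k != active) g(k) = std::max(0.0, N(active, k)) / pop_old(active);
      double gs = accu(g);
      if (gs > 1.0) g /= gs;
    }

    // hop decision
    double r = unif(rng);
    int target = -1;
    double cum = 0.0;
    for (int k = 0; k < n_states; ++k) {
      if (k == active) continue;
      cum += g(k);
      if (r < cum) { target = k; break; }
    }

    x = x_new; v = v_new; E = E_new; U = U_new; G = G_new; c = c_new;
    g_act = g_new;

    if (target >= 0) {
      double gap = E(target) - E(active);
      double ke = kinetic(v);
      if (ke > gap) {
        double fac = std::sqrt(1.0 - gap / ke);
        v *= fac;
        hop_t.push_back(step * dt);
        hop_from.push_back(active);
        hop_to.push_back(target);
        hop_gap.push_back(std::abs(gap));
        hop_x.push_back(conv_to<std::vector<double>>::from(x));
        active = target;
        g_act = adiab_grad(G, U, active);
        etot_ref = kinetic(v) + E(active);
        aux_dx.zeros(); aux_dp.zeros();
      } else if (frustrated_policy == 1) {
        v *= -1.0;
      }
    }

    // decoherence correction
    if (deco_scheme == 1) {
      // frozen-Gaussian auxiliary displacement per non-active state
      bool collapsed = false;
      for (int k = 0; k < n_states && !collapsed; ++k) {
        if (k == active || std::abs(c(k)) < 1e-12) continue;
        vec gk = adiab_grad(G, U, k);
        aux_dp.col(k) += (g_act - gk) * dt; // force difference (eV/A) * fs
        aux_dx.col(k) += aux_dp.col(k) / (masses * AMU_A2FS2_TO_EV) * dt;
        double arg = accu(masses % square(aux_dx.col(k))) /
                     (4.0 * deco_width * deco_width);
        if (std::exp(-arg) < deco_threshold) {
          cx_double ca = c(active);
          c.zeros();
          c(active) = (std::abs(ca) > 0) ? ca / std::abs(ca) : cx_double(1, 0);
          aux_dx.zeros(); aux_dp.zeros();
          collapsed = true;
        }
      }
    } else if (deco_scheme == 2) {
      double ke = kinetic(v);
      for (int k = 0; k < n_states; ++k) {
        if (k == active) continue;
        double gap = std::abs(E(k) - E(active));
        if (gap < 1e-12) continue;
        double tau = HBAR_EVFS / gap * (1.0 + deco_const / std::max(ke, 1e-8));
        c(k) *= std::exp(-dt / tau);
      }
      double pa = accu(square(abs(c))) - std::norm(c(active));
      double target_pa = 1.0 - pa;
      if (std::abs(c(active)) > 1e-14 && target_pa > 0)
        c(active) *= std::sqrt(target_pa) / std::abs(c(active));
    }
    // renormalize (guards slow drift; unitary propagation keeps this ~1)
    c /= std::sqrt(accu(square(abs(c))));

    double drift = std::abs(kinetic(v) + E(active) - etot_ref);
    if (drift > energy_tol * std::max(1.0, step * dt / 1000.0))
      Rcpp::stop("energy conservation failure at step %d (drift %g eV)",
                 step, drift);

    if (step % record_stride == 0) record(step * dt);
    step_done = step;
    if (exit_abs_coord > 0 && std::abs(x(0)) > exit_abs_coord) {
      exited = true;
      break;
    }
  }

  int nh = hop_t.size();
  mat hop_geom(nh, nd);
  for (int i = 0; i < nh; ++i)
    hop_geom.row(i) = conv_to<rowvec>::from(vec(hop_x[i])).eval();

  return Rcpp::List::create(
      Rcpp::Named("time") = rec_t.head(irec),
      Rcpp::Named("coords") = rec_x.head_rows(irec),
      Rcpp::Named("velocities") = rec_v.head_rows(irec),
      Rcpp::Named("energies") = rec_E.head_rows(irec),
      Rcpp::Named("coeffs_re") = mat(real(rec_c.head_rows(irec))),
      Rcpp::Named("coeffs_im") = mat(imag(rec_c.head_rows(irec))),
      Rcpp::Named("active") = rec_state.head(irec),
      Rcpp::Named("dipoles") = rec_dip.head_rows(irec),
      Rcpp::Named("hop_time") = hop_t,
      Rcpp::Named("hop_from") = hop_from,
      Rcpp::Named("hop_to") = hop_to,
      Rcpp::Named("hop_gap") = hop_gap,
      Rcpp::Named("hop_coords") = hop_geom,
      Rcpp::Named("final_coords") = x,
      Rcpp::Named("final_velocities") = v,
      Rcpp::Named("final_state") = active,
      Rcpp::Named("steps") = step_done,
      Rcpp::Named("exited") = exited);
}
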