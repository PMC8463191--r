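#include <Rcpp.h>
#include <cmath>

// Fixed-step RK4 core for the two-module, eight-population thalamocortical
// model. State layout (shared contract with the R side):
//   0 PY1, 1 IN1, 2 SRN1, 3 TRN1, 4 PY2, 5 IN2, 6 SRN2, 7 TRN2
//
// The stimulation waveform and gating are evaluated analytically at every
// RK4 sub-step time, so the recorded stimulus trace is exactly the waveform
// the R-level generators produce on the same grid.

namespace {

struct Pars {
  double h1, h2, h3, h4, h5, h6, h7, h8, h9;
  double eps_py, eps_in, eps_srn, eps_trn;
  double tau1, tau2, tau3, tau4;
  double a, b, k;         // k = log(eps_sigmoid)
  double cross;           // 1/intermodule_scale
  double g1, g2;          // cross-term gain into module 1 / module 2
  double xtau1, xtau2, xtau3, xtau4; // tau factors on cross terms (1 or tau_i)
};

struct Stim {
  int kind;               // 0 none, 1 dbs, 2 cbbp, 3 crs
  double alpha, rho, delta, T;
  int m, n;
  double cycle;
  bool literal;           // CBBP: printed-form amplitudes (delta-valued)
};

inline double Q(double x, double k) {
  double z = -k * x;
  if (z > 700.0) return 0.0;
  if (z < -700.0) return 1.0;
  return 1.0 / (1.0 + std::exp(z));
}

// phase inside one period, with a relative-epsilon tie-break so that grid
// times landing (up to rounding) on a period boundary count as phase 0 and
// times landing on the pulse edge count as OFF: the pulse is [0, delta)
inline double period_phase(double t, double P) {
  double phase = t - P * std::floor(t / P);
  if (P - phase < 1e-9 * P) phase = 0.0;
  return phase;
}

inline double dbs_u(double t, const Stim& s) {
  double phase = period_phase(t, s.rho);
  return (phase < s.delta - 1e-9 * s.rho) ? s.alpha : 0.0;
}

inline double cbbp_u(double t, const Stim& s) {
  double phase = period_phase(t, s.T);
  // literal printed form: amplitudes (delta, -delta/(T-delta)), which is
  // NOT charge balanced; balanced form: (alpha, -alpha*delta/(T-delta))
  double ap = s.literal ? s.delta : s.alpha;
  double cp = s.literal ? (-s.delta / (s.T - s.delta))
                        : (-s.alpha * s.delta / (s.T - s.delta));
  return (phase < s.delta - 1e-9 * s.T) ? ap : cp;
}

// beta gates; also sets u for the CRS carrier pulse train
inline void gates(double t, const Stim& s, double& b1, double& b2) {
  switch (s.kind) {
  case 0: b1 = 0.0; b2 = 0.0; break;
  case 1: case 2: b1 = 1.0; b2 = 1.0; break;
  default: {
    long long cyc = (long long)std::floor(t / s.cycle + 1e-9);
    long long sp  = s.m + s.n;
    long long pos = cyc % sp;
    if (pos < s.m) {
      long long on_idx = (cyc / sp) * s.m + pos;
      if (on_idx % 2 == 0) { b1 = 1.0; b2 = 0.0; }
      else                 { b1 = 0.0; b2 = 1.0; }
    } else { b1 = 0.0; b2 = 0.0; }
  }
  }
}

inline void stim_at(double t, const Stim& s, double& s1, double& s2) {
  if (s.kind == 0) { s1 = 0.0; s2 = 0.0; return; }
  double u = (s.kind == 2) ? cbbp_u(t, s) : dbs_u(t, s);
  double b1, b2;
  gates(t, s, b1, b2);
  s1 = b1 * u; s2 = b2 * u;
}

inline void deriv(const double* y, const Pars& p, double s1, double s2,
                  double* d) {
  double q_py1 = Q(y[0], p.k), q_in1 = Q(y[1], p.k), q_sr1 = Q(y[2], p.k);
  double q_py2 = Q(y[4], p.k), q_in2 = Q(y[5], p.k), q_sr2 = Q(y[6], p.k);
  double k_sr1 = p.a * y[2] + p.b, k_tr1 = p.a * y[3] + p.b;
  double k_sr2 = p.a * y[6] + p.b, k_tr2 = p.a * y[7] + p.b;
  double c = p.cross;

  d[0] = (p.eps_py - y[0] + p.h1 * q_py1 - p.h2 * q_in1 + p.h3 * q_sr1) * p.tau1
       + p.g1 * p.xtau1 * c * (p.h1 * q_py2 - p.h2 * q_in2);
  d[4] = (p.eps_py - y[4] + p.h1 * q_py2 - p.h2 * q_in2 + p.h3 * q_sr2) * p.tau1
       + p.g2 * p.xtau1 * c * (p.h1 * q_py1 - p.h2 * q_in1);
  d[1] = (p.eps_in - y[1] + p.h4 * q_py1) * p.tau2
       + p.g1 * p.xtau2 * c * p.h4 * q_py2;
  d[5] = (p.eps_in - y[5] + p.h4 * q_py2) * p.tau2
       + p.g2 * p.xtau2 * c * p.h4 * q_py1;
  d[2] = (p.eps_srn - y[2] + p.h5 * q_py1 - p.h6 * k_tr1) * p.tau3
       - p.g1 * p.xtau3 * c * p.h6 * k_tr2;
  d[6] = (p.eps_srn - y[6] + p.h5 * q_py2 - p.h6 * k_tr2) * p.tau3
       - p.g2 * p.xtau3 * c * p.h6 * k_tr1;
  d[3] = (p.eps_trn - y[3] + p.h7 * q_py1 + p.h8 * k_sr1 - p.h9 * k_tr1) * p.tau4
       + p.g1 * p.xtau4 * c * (p.h8 * k_sr2 - p.h9 * k_tr2) + s1;
  d[7] = (p.eps_trn - y[7] + p.h7 * q_py2 + p.h8 * k_sr2 - p.h9 * k_tr2) * p.tau4
       + p.g2 * p.xtau4 * c * (p.h8 * k_sr1 - p.h9 * k_tr1) + s2;
}

Pars unpack_pars(const Rcpp::List& par) {
  Pars p;
  Rcpp::NumericVector h = par["h"];
  p.h1 = h[0]; p.h2 = h[1]; p.h3 = h[2]; p.h4 = h[3]; p.h5 = h[4];
  p.h6 = h[5]; p.h7 = h[6]; p.h8 = h[7]; p.h9 = h[8];
  Rcpp::NumericVector eps = par["eps"];
  p.eps_py = eps[0]; p.eps_in = eps[1]; p.eps_srn = eps[2]; p.eps_trn = eps[3];
  Rcpp::NumericVector tau = par["tau"];
  p.tau1 = tau[0]; p.tau2 = tau[1]; p.tau3 = tau[2]; p.tau4 = tau[3];
  p.a = Rcpp::as<double>(par["a"]);
  p.b = Rcpp::as<double>(par["b"]);
  p.k = std::log(Rcpp::as<double>(par["eps_sigmoid"]));
  p.cross = 1.0 / Rcpp::as<double>(par["intermodule_scale"]);
  int topo = Rcpp::as<int>(par["topology_code"]); // 0 bi, 1 uni, 2 uncoupled
  // unidirectional: the observed module I is driven by an autonomous
  // module II (cross input into module I only)
  p.g1 = (topo <= 1) ? 1.0 : 0.0;
  p.g2 = (topo == 0) ? 1.0 : 0.0;
  bool cit = Rcpp::as<bool>(par["cross_inside_tau"]);
  p.xtau1 = cit ? p.tau1 : 1.0; p.xtau2 = cit ? p.tau2 : 1.0;
  p.xtau3 = cit ? p.tau3 : 1.0; p.xtau4 = cit ? p.tau4 : 1.0;
  return p;
}

Stim unpack_stim(const Rcpp::List& st) {
  Stim s;
  s.kind = Rcpp::as<int>(st["kind_code"]);
  s.alpha = Rcpp::as<double>(st["amplitude"]);
  s.rho = Rcpp::as<double>(st["period"]);
  s.delta = Rcpp::as<double>(st["pulse_width"]);
  s.T = Rcpp::as<double>(st["cbbp_period"]);
  s.m = Rcpp::as<int>(st["crs_m"]);
  s.n = Rcpp::as<int>(st["crs_n"]);
  s.cycle = Rcpp::as<double>(st["crs_cycle"]);
  s.literal = Rcpp::as<bool>(st["cbbp_literal"]);
  return s;
}

} // namespace

// [[Rcpp::export(name = ".rk4_integrate")]]
Rcpp::List rk4_integrate(Rcpp::NumericVector y0, Rcpp::List par,
                         Rcpp::List stim, double dt, int n_steps,
                         int record_every, double overflow_guard) {
  Pars p = unpack_pars(par);
  Stim s = unpack_stim(stim);

  int n_rec = n_steps / record_every + 1;
  Rcpp::NumericMatrix states(n_rec, 8);
  Rcpp::NumericVector time(n_rec), s1_rec(n_rec), s2_rec(n_rec);

  double y[8], yt[8], k1[8], k2[8], k3[8], k4[8];
  for (int j = 0; j < 8; ++j) y[j] = y0[j];

  bool diverged = false;
  double t_div = NA_REAL;
  int ir = 0;

  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (i % record_every == 0 && ir < n_rec) {
      time[ir] = t;
      for (int j = 0; j < 8; ++j) states(ir, j) = y[j];
      double a1, a2;
      stim_at(t, s, a1, a2);
      s1_rec[ir] = a1; s2_rec[ir] = a2;
      ++ir;
    }
    if (i == n_steps || diverged) {
      if (!diverged) continue; // recorded final point; loop ends
      break;
    }

    double u1, u2;
    stim_at(t, s, u1, u2);
    deriv(y, p, u1, u2, k1);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    stim_at(t + 0.5 * dt, s, u1, u2);
    deriv(yt, p, u1, u2, k2);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    deriv(yt, p, u1, u2, k3);
    for (int j = 0; j < 8; ++j) yt[j] = y[j] + dt * k3[j];
    stim_at(t + dt, s, u1, u2);
    deriv(yt, p, u1, u2, k4);
    for (int j = 0; j < 8; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    for (int j = 0; j < 8; ++j) {
      if (!std::isfinite(y[j]) || std::fabs(y[j]) > overflow_guard) {
        diverged = true;
        t_div = t + dt;
        break;
      }
    }
    if (diverged) break;
  }

  if (diverged && ir < n_rec) {
    // truncate recordings at the divergence point
    Rcpp::NumericMatrix st2(ir, 8);
    Rcpp::NumericVector tm2(ir), r1(ir), r2(ir);
    for (int i = 0; i < ir; ++i) {
      tm2[i] = time[i]; r1[i] = s1_rec[i]; r2[i] = s2_rec[i];
      for (int j = 0; j < 8; ++j) st2(i, j) = states(i, j);
    }
    states = st2; time = tm2; s1_rec = r1; s2_rec = r2;
  }

  return Rcpp::List::create(
    Rcpp::Named("time") = time,
    Rcpp::Named("states") = states,
    Rcpp::Named("stim1") = s1_rec,
    Rcpp::Named("stim2") = s2_rec,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("diverge_time") = t_div);
}

// Single right-hand-side evaluation, used to cross-check the R reference
// implementation against the compiled integrator.
// [[Rcpp::export(name = ".rhs_cpp")]]
Rcpp::NumericVector rhs_cpp(Rcpp::NumericVector state, Rcpp::List par,
                            double stim_trn1, double stim_trn2) {
  Pars p = unpack_pars(par);
  double y[8], d[8];
  for (int j = 0; j < 8; ++j) y[j] = state[j];
  deriv(y, p, stim_trn1, stim_trn2, d);
  Rcpp::NumericVector out(8);
  for (int j = 0; j < 8; ++j) out[j] = d[j];
  return out;
}
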