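// Human ventricular myocyte electrophysiology (ten Tusscher-Panfilov 2006
// formulation) with an external-current injection port used for the pacing
// stimulus and the stretch-activated current.
#include "cardiomef.h"
using namespace Rcpp;

// physical constants
static const double Rgas = 8314.472;   // mJ/(mol K)
static const double Frdy = 96485.3415; // C/mol
static const double Temp = 310.0;      // K
static const double RTF  = Rgas * Temp / Frdy;

// fixed geometry / environment of the published model
static const double Vc   = 0.016404;   // uL, cytoplasm
static const double Vsr  = 0.001094;   // uL, sarcoplasmic reticulum
static const double Vss  = 0.00005468; // uL, dyadic subspace
static const double Ko   = 5.4, Cao = 2.0, Nao = 140.0; // mM
static const double pKNa = 0.03;
// SR calcium handling
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double maxsr = 2.5, minsr = 1.0, EC = 1.5;
// buffering
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
// NaCa exchanger / NaK pump constants
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncx_gamma = 0.35;
static const double alpha_ncx = 2.5;
static const double KmK = 1.0, KmNa = 40.0;

static double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm))
    stop("parameter vector is missing element '%s'", nm);
  return v[nm];
}

CellP cell_from_vec(const NumericVector& p) {
  CellP c;
  c.cell_type = (int) getp(p, "cell_type");
  c.g_na = getp(p, "g_na");  c.g_k1 = getp(p, "g_k1");
  c.g_kr = getp(p, "g_kr");  c.g_ks = getp(p, "g_ks");
  c.g_to = getp(p, "g_to");  c.g_cal = getp(p, "g_cal");
  c.g_bna = getp(p, "g_bna"); c.g_bca = getp(p, "g_bca");
  c.g_pca = getp(p, "g_pca"); c.g_pk = getp(p, "g_pk");
  c.p_nak = getp(p, "p_nak"); c.k_naca = getp(p, "k_naca");
  c.cm = getp(p, "cm");
  return c;
}

SacP sac_from_vec(const NumericVector& p) {
  SacP s;
  s.g = getp(p, "g"); s.e_rev = getp(p, "e_rev");
  s.k_sig = getp(p, "k_sig"); s.alpha = getp(p, "alpha");
  s.enabled = (int) getp(p, "enabled");
  return s;
}

double sac_current(double vm, double lambda, const SacP& s) {
  if (!s.enabled) return 0.0;
  return s.g * (vm - s.e_rev) / (1.0 + s.k_sig * std::exp(-s.alpha * (lambda - 1.0)));
}

struct Gates { double inf[12], tau[12]; }; // states 6..17

// gate steady states and time constants at voltage v (and CaSS for fcass)
static void gate_rates(double v, double cass, int cell_type, Gates& g) {
  // m
  g.inf[0] = 1.0 / std::pow(1.0 + std::exp((-56.86 - v) / 9.03), 2.0);
  {
    double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
    g.tau[0] = am * bm;
  }
  // h
  g.inf[1] = 1.0 / std::pow(1.0 + std::exp((v + 71.55) / 7.43), 2.0);
  {
    double ah, bh;
    if (v >= -40.0) { ah = 0.0; bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1))); }
    else { ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
           bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v); }
    g.tau[1] = 1.0 / (ah + bh);
  }
  // j
  g.inf[2] = g.inf[1];
  {
    double aj, bj;
    if (v >= -40.0) { aj = 0.0;
      bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0))); }
    else {
      aj = (-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v)) *
           (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * v) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
    }
    g.tau[2] = 1.0 / (aj + bj);
  }
  // d
  g.inf[3] = 1.0 / (1.0 + std::exp((-8.0 - v) / 7.5));
  {
    double ad = 1.4 / (1.0 + std::exp((-35.0 - v) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((v + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - v) / 20.0));
    g.tau[3] = ad * bd + gd;
  }
  // f
  g.inf[4] = 1.0 / (1.0 + std::exp((v + 20.0) / 7.0));
  g.tau[4] = 1102.5 * std::exp(-std::pow(v + 27.0, 2.0) / 225.0) +
             200.0 / (1.0 + std::exp((13.0 - v) / 10.0)) +
             180.0 / (1.0 + std::exp((v + 30.0) / 10.0)) + 20.0;
  // f2
  g.inf[5] = 0.67 / (1.0 + std::exp((v + 35.0) / 7.0)) + 0.33;
  g.tau[5] = 562.0 * std::exp(-std::pow(v + 27.0, 2.0) / 240.0) +
             31.0 / (1.0 + std::exp((25.0 - v) / 10.0)) +
             80.0 / (1.0 + std::exp((v + 30.0) / 10.0));
  // fcass (depends on subspace calcium, not voltage)
  {
    double q = std::pow(cass / 0.05, 2.0);
    g.inf[6] = 0.6 / (1.0 + q) + 0.4;
    g.tau[6] = 80.0 / (1.0 + q) + 2.0;
  }
  // r
  g.inf[7] = 1.0 / (1.0 + std::exp((20.0 - v) / 6.0));
  g.tau[7] = 9.5 * std::exp(-std::pow(v + 40.0, 2.0) / 1800.0) + 0.8;
  // s: epicardial/mid vs endocardial kinetics
  if (cell_type == 1) { // endo
    g.inf[8] = 1.0 / (1.0 + std::exp((v + 28.0) / 5.0));
    g.tau[8] = 1000.0 * std::exp(-std::pow(v + 67.0, 2.0) / 1000.0) + 8.0;
  } else {
    g.inf[8] = 1.0 / (1.0 + std::exp((v + 20.0) / 5.0));
    g.tau[8] = 85.0 * std::exp(-std::pow(v + 45.0, 2.0) / 320.0) +
               5.0 / (1.0 + std::exp((v - 20.0) / 5.0)) + 3.0;
  }
  // xr1
  g.inf[9] = 1.0 / (1.0 + std::exp((-26.0 - v) / 7.0));
  {
    double a = 450.0 / (1.0 + std::exp((-45.0 - v) / 10.0));
    double b = 6.0 / (1.0 + std::exp((v + 30.0) / 11.5));
    g.tau[9] = a * b;
  }
  // xr2
  g.inf[10] = 1.0 / (1.0 + std::exp((v + 88.0) / 24.0));
  {
    double a = 3.0 / (1.0 + std::exp((-60.0 - v) / 20.0));
    double b = 1.12 / (1.0 + std::exp((v - 60.0) / 20.0));
    g.tau[10] = a * b;
  }
  // xs
  g.inf[11] = 1.0 / (1.0 + std::exp((-5.0 - v) / 14.0));
  {
    double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - v) / 6.0));
    double b = 1.0 / (1.0 + std::exp((v - 35.0) / 15.0));
    g.tau[11] = a * b + 80.0;
  }
}

struct Currents {
  double ina, ical, ito, iks, ikr, ik1, inaca, inak, ipca, ipk, ibna, ibca;
  double irel, ileak, iup, ixfer;
  double itot; // membrane currents (A/F), external current excluded
};

static void membrane_currents(const double* y, const CellP& p, Currents& c) {
  const double v = y[0], nai = y[1], ki = y[2], cai = y[3], cass = y[4], casr = y[5];
  const double m = y[6], h = y[7], j = y[8], d = y[9], f = y[10], f2 = y[11];
  const double fcass = y[12], r = y[13], s = y[14], xr1 = y[15], xr2 = y[16], xs = y[17];
  const double rbar = y[18];

  const double ena = RTF * std::log(Nao / nai);
  const double ek  = RTF * std::log(Ko / ki);
  const double eks = RTF * std::log((Ko + pKNa * Nao) / (ki + pKNa * nai));
  const double eca = 0.5 * RTF * std::log(Cao / cai);

  c.ina = p.g_na * m * m * m * h * j * (v - ena);

  {
    double vshift = v - 15.0;
    double ex = std::exp(2.0 * vshift / RTF);
    double denom = ex - 1.0;
    double fac;
    if (std::fabs(vshift) < 1e-6) fac = RTF / 2.0; // limit of vshift/denom
    else fac = vshift / denom;
    c.ical = p.g_cal * d * f * f2 * fcass * 4.0 * fac * (Frdy / RTF) *
             (0.25 * cass * ex - Cao);
  }

  c.ito = p.g_to * r * s * (v - ek);
  c.iks = p.g_ks * xs * xs * (v - eks);
  c.ikr = p.g_kr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (v - ek);

  {
    double ak1 = 0.1 / (1.0 + std::exp(0.06 * (v - ek - 200.0)));
    double bk1 = (3.0 * std::exp(0.0002 * (v - ek + 100.0)) +
                  std::exp(0.1 * (v - ek - 10.0))) /
                 (1.0 + std::exp(-0.5 * (v - ek)));
    c.ik1 = p.g_k1 * std::sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (v - ek);
  }

  {
    double e1 = std::exp(ncx_gamma * v / RTF);
    double e2 = std::exp((ncx_gamma - 1.0) * v / RTF);
    c.inaca = p.k_naca *
      (e1 * nai * nai * nai * Cao - e2 * Nao * Nao * Nao * cai * alpha_ncx) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * e2));
  }

  c.inak = p.p_nak * Ko * nai /
           ((Ko + KmK) * (nai + KmNa) *
            (1.0 + 0.1245 * std::exp(-0.1 * v / RTF) + 0.0353 * std::exp(-v / RTF)));

  c.ipca = p.g_pca * cai / (cai + 0.0005);
  c.ipk  = p.g_pk * (v - ek) / (1.0 + std::exp((25.0 - v) / 5.98));
  c.ibna = p.g_bna * (v - ena);
  c.ibca = p.g_bca * (v - eca);

  // SR fluxes
  {
    double kcasr = maxsr - (maxsr - minsr) / (1.0 + std::pow(EC / casr, 2.0));
    double k1 = k1p / kcasr;
    double oo = k1 * cass * cass * rbar / (k3 + k1 * cass * cass);
    c.irel = Vrel * oo * (casr - cass);
  }
  c.ileak = Vleak * (casr - cai);
  c.iup   = Vmaxup / (1.0 + (Kup * Kup) / (cai * cai));
  c.ixfer = Vxfer * (cass - cai);

  c.itot = c.ina + c.ical + c.ito + c.iks + c.ikr + c.ik1 + c.inaca + c.inak +
           c.ipca + c.ipk + c.ibna + c.ibca;
}

// Full right-hand side; i_ext (A/F) is added to the membrane current sum.
void cell_derivs(const double* y, const CellP& p, double i_ext, double* dy) {
  Currents c;
  membrane_currents(y, p, c);
  Gates g;
  gate_rates(y[0], y[4], p.cell_type, g);

  const double cai = y[3], cass = y[4], casr = y[5], rbar = y[18];
  const double cm_vcf = p.cm / (Vc * Frdy);

  dy[0] = -(c.itot + i_ext);
  dy[1] = -(c.ina + c.ibna + 3.0 * c.inak + 3.0 * c.inaca) * cm_vcf;
  // stimulus/external current assigned to K+ as is conventional
  dy[2] = -(c.ik1 + c.ito + c.ikr + c.iks - 2.0 * c.inak + c.ipk + i_ext) * cm_vcf;

  double bufc_f  = 1.0 / (1.0 + Bufc * Kbufc / std::pow(cai + Kbufc, 2.0));
  double bufsr_f = 1.0 / (1.0 + Bufsr * Kbufsr / std::pow(casr + Kbufsr, 2.0));
  double bufss_f = 1.0 / (1.0 + Bufss * Kbufss / std::pow(cass + Kbufss, 2.0));

  dy[3] = bufc_f * ((c.ileak - c.iup) * Vsr / Vc + c.ixfer -
                    (c.ibca + c.ipca - 2.0 * c.inaca) * p.cm / (2.0 * Vc * Frdy));
  dy[4] = bufss_f * (-c.ical * p.cm / (2.0 * Vss * Frdy) +
                     c.irel * Vsr / Vss - c.ixfer * Vc / Vss);
  dy[5] = bufsr_f * (c.iup - c.irel - c.ileak);

  for (int k = 0; k < 12; ++k)
    dy[6 + k] = (g.inf[k] - y[6 + k]) / g.tau[k];

  {
    double kcasr = maxsr - (maxsr - minsr) / (1.0 + std::pow(EC / casr, 2.0));
    double k2 = k2p * kcasr;
    dy[18] = -k2 * cass * rbar + k4 * (1.0 - rbar);
  }
}

// One fixed step: exponential (Rush-Larsen) update for the 12 HH gates and
// the RyR availability, forward Euler for potential and concentrations.
void cell_step_rl(double* y, const CellP& p, double i_ext, double dt) {
  Currents c;
  membrane_currents(y, p, c);
  Gates g;
  gate_rates(y[0], y[4], p.cell_type, g);

  const double cai = y[3], cass = y[4], casr = y[5];
  const double cm_vcf = p.cm / (Vc * Frdy);

  double dv   = -(c.itot + i_ext);
  double dnai = -(c.ina + c.ibna + 3.0 * c.inak + 3.0 * c.inaca) * cm_vcf;
  double dki  = -(c.ik1 + c.ito + c.ikr + c.iks - 2.0 * c.inak + c.ipk + i_ext) * cm_vcf;

  double bufc_f  = 1.0 / (1.0 + Bufc * Kbufc / std::pow(cai + Kbufc, 2.0));
  double bufsr_f = 1.0 / (1.0 + Bufsr * Kbufsr / std::pow(casr + Kbufsr, 2.0));
  double bufss_f = 1.0 / (1.0 + Bufss * Kbufss / std::pow(cass + Kbufss, 2.0));

  double dcai  = bufc_f * ((c.ileak - c.iup) * Vsr / Vc + c.ixfer -
                 (c.ibca + c.ipca - 2.0 * c.inaca) * p.cm / (2.0 * Vc * Frdy));
  double dcass = bufss_f * (-c.ical * p.cm / (2.0 * Vss * Frdy) +
                 c.irel * Vsr / Vss - c.ixfer * Vc / Vss);
  double dcasr = bufsr_f * (c.iup - c.irel - c.ileak);

  y[0] += dt * dv;
  y[1] += dt * dnai;
  y[2] += dt * dki;
  y[3] = std::max(1e-12, cai + dt * dcai);
  y[4] = std::max(1e-12, cass + dt * dcass);
  y[5] = std::max(1e-12, casr + dt * dcasr);

  for (int k = 0; k < 12; ++k) {
    double e = std::exp(-dt / g.tau[k]);
    y[6 + k] = g.inf[k] + (y[6 + k] - g.inf[k]) * e;
  }

  {
    double kcasr = maxsr - (maxsr - minsr) / (1.0 + std::pow(EC / casr, 2.0));
    double rate = k2p * kcasr * cass + k4;
    double rinf = k4 / rate;
    y[18] = rinf + (y[18] - rinf) * std::exp(-dt * rate);
  }
}

static void check_state(const NumericVector& s) {
  if (s.size() != N_CELL_STATE) stop("cell state must have %d entries", N_CELL_STATE);
  for (int i = 0; i < s.size(); ++i)
    if (!R_finite(s[i])) stop("non-finite cell state component at position %d", i + 1);
}

// [[Rcpp::export]]
NumericVector cpp_cell_derivs(NumericVector state, NumericVector params,
                              double i_external) {
  check_state(state);
  CellP p = cell_from_vec(params);
  NumericVector out(N_CELL_STATE);
  cell_derivs(REAL(state), p, i_external, REAL(out));
  out.attr("names") = state.attr("names");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_step_cell(NumericVector state, NumericVector params,
                            double i_external, double dt) {
  if (dt <= 0) stop("dt must be positive");
  check_state(state);
  CellP p = cell_from_vec(params);
  NumericVector out = clone(state);
  cell_step_rl(REAL(out), p, i_external, dt);
  return out;
}

// Run an isolated cell for `duration` ms under a rectangular stimulus and a
// (possibly time-varying) stretch driving the stretch-activated current.
// lambda_t: either length-1 (constant) or sampled every dt.
// [[Rcpp::export]]
List cpp_run_cell(NumericVector state, NumericVector params,
                  NumericVector sac_params, NumericVector lambda_t,
                  double duration, double dt,
                  double stim_onset, double stim_dur, double stim_amp,
                  double record_every) {
  check_state(state);
  CellP p = cell_from_vec(params);
  SacP sac = sac_from_vec(sac_params);

  int nstep = (int) std::llround(duration / dt);
  int stride = std::max(1, (int) std::llround(record_every / dt));
  int nrec = nstep / stride + 1;
  bool lam_const = lambda_t.size() == 1;
  if (!lam_const && lambda_t.size() < nstep)
    stop("lambda_t must be length 1 or cover every time step");

  NumericMatrix trace(nrec, 4); // time, vm, cai, lambda
  std::vector<double> y(REAL(state), REAL(state) + N_CELL_STATE);

  int irec = 0;
  double lam0 = lam_const ? lambda_t[0] : lambda_t[0];
  trace(irec, 0) = 0.0; trace(irec, 1) = y[0]; trace(irec, 2) = y[3];
  trace(irec, 3) = lam0; ++irec;

  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    double lam = lam_const ? lambda_t[0] : lambda_t[i];
    double iext = sac_current(y[0], lam, sac);
    if (t >= stim_onset && t < stim_onset + stim_dur) iext += stim_amp;
    cell_step_rl(y.data(), p, iext, dt);
    if ((i + 1) % stride == 0 && irec < nrec) {
      trace(irec, 0) = t + dt; trace(irec, 1) = y[0]; trace(irec, 2) = y[3];
      trace(irec, 3) = lam; ++irec;
    }
  }

  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = state.attr("names");
  colnames(trace) = CharacterVector::create("time_ms", "vm_mv", "cai_mm", "lambda");
  return List::create(_["trace"] = trace, _["state"] = fin);
}

// Pace an isolated, unstretched cell to its periodic steady state.
// [[Rcpp::export]]
List cpp_pace_cell(NumericVector state, NumericVector params,
                   double cycle_length, int n_beats_max, double tol,
                   double dt, double stim_dur, double stim_amp) {
  check_state(state);
  CellP p = cell_from_vec(params);
  std::vector<double> y(REAL(state), REAL(state) + N_CELL_STATE);
  std::vector<double> yprev(y);

  int nstep = (int) std::llround(cycle_length / dt);
  bool converged = false;
  double delta = NA_REAL;
  int beats = 0;

  for (int b = 0; b < n_beats_max; ++b) {
    yprev = y;
    for (int i = 0; i < nstep; ++i) {
      double t = i * dt;
      double iext = (t < stim_dur) ? stim_amp : 0.0;
      cell_step_rl(y.data(), p, iext, dt);
    }
    ++beats;
    delta = 0.0;
    for (int k = 0; k < N_CELL_STATE; ++k) {
      double rel = std::fabs(y[k] - yprev[k]) / (std::fabs(yprev[k]) + 1e-8);
      if (rel > delta) delta = rel;
    }
    if (delta < tol) { converged = true; break; }
  }

  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = state.attr("names");
  return List::create(_["state"] = fin, _["beats"] = beats,
                      _["converged"] = converged, _["delta"] = delta);
}
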