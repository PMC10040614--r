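// Closed-loop coupling: lumped circulation (8 compartment volumes + 4 valve
// flows) strongly coupled to two multi-patch thin-wall ventricles, with
// staggered electrophysiology / active-tension substepping.
#include "cardiomef.h"
using namespace Rcpp;

static const double KPA_TO_MMHG = 7.50061683;

static double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm))
    stop("parameter vector is missing element '%s'", nm);
  return v[nm];
}

struct CircP {
  double c_sa, c_sv, c_pa, c_pv;
  double v0_sa, v0_sv, v0_pa, v0_pv;
  double r_sys, r_sv, r_pul, r_pv;
  double e_min_ra, e_max_ra, v0_ra, e_min_la, e_max_la, v0_la;
  double t_atr_dur, ra_onset, la_delay;
  double ropen[4], rclosed[4], inert[4], rlin[4]; // mv, av, tv, pv
};

static CircP circ_from_vec(const NumericVector& p) {
  CircP c;
  c.c_sa = getp(p, "c_sa"); c.c_sv = getp(p, "c_sv");
  c.c_pa = getp(p, "c_pa"); c.c_pv = getp(p, "c_pv");
  c.v0_sa = getp(p, "v0_sa"); c.v0_sv = getp(p, "v0_sv");
  c.v0_pa = getp(p, "v0_pa"); c.v0_pv = getp(p, "v0_pv");
  c.r_sys = getp(p, "r_sys"); c.r_sv = getp(p, "r_sv");
  c.r_pul = getp(p, "r_pul"); c.r_pv = getp(p, "r_pv");
  c.e_min_ra = getp(p, "e_min_ra"); c.e_max_ra = getp(p, "e_max_ra");
  c.v0_ra = getp(p, "v0_ra");
  c.e_min_la = getp(p, "e_min_la"); c.e_max_la = getp(p, "e_max_la");
  c.v0_la = getp(p, "v0_la");
  c.t_atr_dur = getp(p, "t_atr_dur");
  c.ra_onset = getp(p, "ra_onset"); c.la_delay = getp(p, "la_delay");
  const char* vn[4] = {"mv", "av", "tv", "pv"};
  for (int k = 0; k < 4; ++k) {
    std::string base(vn[k]);
    c.ropen[k] = getp(p, (base + "_ropen").c_str());
    c.rclosed[k] = getp(p, (base + "_rclosed").c_str());
    c.inert[k] = getp(p, (base + "_inert").c_str());
    c.rlin[k] = getp(p, (base + "_rlin").c_str());
  }
  return c;
}

// periodic remainder in [0, m) without libm's fmod
static double pmod(double x, double m) {
  return x - m * std::floor(x / m);
}

// smooth single-peak atrial activation, period = cycle length
static double atrial_act(double t_cycle, double onset, double dur, double cl) {
  double ph = pmod(t_cycle - onset, cl);
  if (ph >= dur) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * ph / dur));
}

// semi-implicit valve flow: solve a*q|q| + b*q = c for q (a,b > 0)
static double solve_valve_q(double a, double b, double c) {
  if (c >= 0.0) return (-b + std::sqrt(b * b + 4.0 * a * c)) / (2.0 * a);
  return (b - std::sqrt(b * b - 4.0 * a * c)) / (2.0 * a);
}

// diode with inertia: smooth blend between open and closed resistance based
// on the driving term (pressure gradient plus inertial memory)
static double valve_update(double q, double dp, double ropen, double rclosed,
                           double rlin, double L, double h) {
  double b = L / h + rlin; // inertial memory + laminar resistance
  double c = dp + (L / h) * q;
  double w = 1.0 / (1.0 + std::exp(-c / 0.01)); // 0.01 mmHg blending window
  double qo = solve_valve_q(ropen, b, c);
  double qc = solve_valve_q(rclosed, b, c);
  return w * qo + (1.0 - w) * qc;
}

struct CircS {
  // volumes (mL): sa sv pa pv ra la lv rv; flows (mL/ms): mv av tv pv
  double v[8];
  double q[4];
};

enum { SA, SV, PA, PV, RA, LA, LV, RV };
enum { MV, AV, TV, PVV };

// advance circulation by dt; ventricular pressures follow the local
// linearization p = p0 + e (V - V0) around the current equilibrium point
static void circ_advance(CircS& s, const CircP& p,
                         double p_lv0, double e_lv, double v_lv0,
                         double p_rv0, double e_rv, double v_rv0,
                         double t_cycle, double cl, double dt, int nsub,
                         double* q_mean = 0) {
  double h = dt / nsub;
  for (int k = 0; k < nsub; ++k) {
    double t = t_cycle + k * h;
    double p_lv = p_lv0 + e_lv * (s.v[LV] - v_lv0);
    double p_rv = p_rv0 + e_rv * (s.v[RV] - v_rv0);
    double p_sa = (s.v[SA] - p.v0_sa) / p.c_sa;
    double p_sv = (s.v[SV] - p.v0_sv) / p.c_sv;
    double p_pa = (s.v[PA] - p.v0_pa) / p.c_pa;
    double p_pv = (s.v[PV] - p.v0_pv) / p.c_pv;
    double a_ra = atrial_act(t, p.ra_onset, p.t_atr_dur, cl);
    double a_la = atrial_act(t, p.ra_onset + p.la_delay, p.t_atr_dur, cl);
    double p_ra = (p.e_min_ra + (p.e_max_ra - p.e_min_ra) * a_ra) * (s.v[RA] - p.v0_ra);
    double p_la = (p.e_min_la + (p.e_max_la - p.e_min_la) * a_la) * (s.v[LA] - p.v0_la);

    double q_sys = (p_sa - p_sv) / p.r_sys;
    double q_sv = (p_sv - p_ra) / p.r_sv;
    double q_pul = (p_pa - p_pv) / p.r_pul;
    double q_pvn = (p_pv - p_la) / p.r_pv;

    s.q[MV] = valve_update(s.q[MV], p_la - p_lv, p.ropen[MV], p.rclosed[MV], p.rlin[MV], p.inert[MV], h);
    s.q[AV] = valve_update(s.q[AV], p_lv - p_sa, p.ropen[AV], p.rclosed[AV], p.rlin[AV], p.inert[AV], h);
    s.q[TV] = valve_update(s.q[TV], p_ra - p_rv, p.ropen[TV], p.rclosed[TV], p.rlin[TV], p.inert[TV], h);
    s.q[PVV] = valve_update(s.q[PVV], p_rv - p_pa, p.ropen[PVV], p.rclosed[PVV], p.rlin[PVV], p.inert[PVV], h);

    s.v[SA] += h * (s.q[AV] - q_sys);
    s.v[SV] += h * (q_sys - q_sv);
    s.v[RA] += h * (q_sv - s.q[TV]);
    s.v[RV] += h * (s.q[TV] - s.q[PVV]);
    s.v[PA] += h * (s.q[PVV] - q_pul);
    s.v[PV] += h * (q_pul - q_pvn);
    s.v[LA] += h * (q_pvn - s.q[MV]);
    s.v[LV] += h * (s.q[MV] - s.q[AV]);
    if (q_mean)
      for (int j = 0; j < 4; ++j) q_mean[j] += s.q[j] / nsub;
  }
}

struct VentGeom {
  std::vector<int> idx;        // patch indices
  std::vector<double> aref, vwall;
  double vwall_tot;
};

// cavity pressure of one thin-wall spherical ventricle at volume V
static double vent_pressure(double V, VentGeom& g,
                            const std::vector<double>& ta_scale_all,
                            double beta0_eff, const PassP& pp,
                            const std::vector<double>& lam_prev_all,
                            double eta_dt,
                            std::vector<double>& areas, // warm start, per-vent
                            std::vector<double>& lam_out, double& tension) {
  double vm = V + 0.5 * g.vwall_tot;
  double r = std::cbrt(3.0 * vm / (4.0 * M_PI));
  double a_mid = 4.0 * M_PI * r * r;
  int n = (int) g.idx.size();
  std::vector<double> ts(n), lp(n);
  for (int i = 0; i < n; ++i) {
    ts[i] = ta_scale_all[g.idx[i]];
    lp[i] = lam_prev_all[g.idx[i]];
  }
  double t = 0.0;
  int it = patch_equilibrium_solve(g.aref, g.vwall, ts, beta0_eff, pp, a_mid,
                                   lp, eta_dt, areas, t);
  if (it < 0) {
    // retry from a uniform-stretch start before giving up
    double s = a_mid;
    double tot = 0.0;
    for (double a : g.aref) tot += a;
    for (int i = 0; i < n; ++i) areas[i] = g.aref[i] * s / tot;
    it = patch_equilibrium_solve(g.aref, g.vwall, ts, beta0_eff, pp, a_mid,
                                 lp, eta_dt, areas, t);
    if (it < 0) stop("ventricular wall equilibrium failed to converge");
  }
  tension = t;
  lam_out.resize(n);
  for (int i = 0; i < n; ++i) lam_out[i] = std::sqrt(areas[i] / g.aref[i]);
  return KPA_TO_MMHG * 2.0 * t / r; // T in kPa*cm, r in cm -> kPa -> mmHg
}

// [[Rcpp::export]]
List cpp_run_heart(List config, List state, int n_beats, double record_every) {
  // --- unpack configuration ---
  CellP cellp = cell_from_vec(config["cell"]);
  SacP sacp = sac_from_vec(config["sac"]);
  LandP landp = land_from_vec(config["land"]);
  PassP passp = pass_from_vec(config["passive"]);
  CircP circp = circ_from_vec(config["circ"]);
  NumericVector tgl = config["toggles"];
  bool vel_on = getp(tgl, "velocity_dependence") != 0;
  bool len_on = getp(tgl, "length_dependence") != 0;
  sacp.enabled = sacp.enabled && (getp(tgl, "sac_enabled") != 0);

  NumericVector passive_vec = config["passive"];
  double eta_wall = passive_vec.containsElementNamed("eta")
    ? (double) passive_vec["eta"] : 0.0;

  NumericVector tim = config["timing"];
  double cl = getp(tim, "cycle_length");
  double dt_mech = getp(tim, "dt_mech");
  int ep_sub = (int) getp(tim, "ep_substeps");
  int ten_every = (int) getp(tim, "tension_every");
  int n_circ_sub = (int) getp(tim, "circ_substeps");
  double stim_dur = getp(tim, "stim_dur");
  double stim_amp = getp(tim, "stim_amp");
  double dt_ep = dt_mech / ep_sub;
  double dt_ten = dt_ep * ten_every;

  List patches = config["patches"];
  IntegerVector p_vent = patches["ventricle"]; // 0 LV, 1 RV
  NumericVector p_aref = patches["aref"];
  NumericVector p_vwall = patches["vwall"];
  NumericVector p_tact = patches["t_act"];
  int np = p_vent.size();

  VentGeom lv, rv;
  for (int i = 0; i < np; ++i) {
    VentGeom& g = (p_vent[i] == 0) ? lv : rv;
    g.idx.push_back(i);
    g.aref.push_back(p_aref[i]);
    g.vwall.push_back(p_vwall[i]);
  }
  lv.vwall_tot = 0.0; for (double w : lv.vwall) lv.vwall_tot += w;
  rv.vwall_tot = 0.0; for (double w : rv.vwall) rv.vwall_tot += w;
  if (lv.idx.empty() || rv.idx.empty())
    stop("each ventricle needs at least one patch");

  // --- unpack state ---
  NumericMatrix cells0 = state["cells"]; // 19 x np
  NumericMatrix land0 = state["land"];   // 6 x np
  if (cells0.ncol() != np || land0.ncol() != np)
    stop("state matrices do not match the number of patches");
  std::vector<std::vector<double>> cells(np), land(np);
  for (int i = 0; i < np; ++i) {
    cells[i].assign(cells0(_, i).begin(), cells0(_, i).end());
    land[i].assign(land0(_, i).begin(), land0(_, i).end());
  }
  NumericVector circ0 = state["circ"];
  CircS circ;
  for (int k = 0; k < 8; ++k) circ.v[k] = circ0[k];
  for (int k = 0; k < 4; ++k) circ.q[k] = circ0[8 + k];
  NumericVector lam0 = state["lambda"];
  std::vector<double> lambda(lam0.begin(), lam0.end());
  NumericVector areas0 = state["areas"];
  std::vector<double> areas_lv, areas_rv;
  for (size_t i = 0; i < lv.idx.size(); ++i) areas_lv.push_back(areas0[lv.idx[i]]);
  for (size_t i = 0; i < rv.idx.size(); ++i) areas_rv.push_back(areas0[rv.idx[i]]);
  double p_lv = as<double>(state["p_lv"]);
  double p_rv = as<double>(state["p_rv"]);

  // --- recording ---
  int steps_per_beat = (int) std::llround(cl / dt_mech);
  int rec_stride = std::max(1, (int) std::llround(record_every / dt_mech));
  int nrec = (n_beats * steps_per_beat) / rec_stride + 1;
  const int NH = 24;
  NumericMatrix hemo(nrec, NH);
  NumericMatrix ptr(nrec * np, 8);
  int irec = 0;
  int max_fp_iters = 0;
  bool fp_converged = true;
  double q_acc[4] = {0, 0, 0, 0}; // step-averaged valve flows per record
  int q_n = 0;

  std::vector<double> ta_scale(np), lam_lv, lam_rv;
  std::vector<double> lambda_dot(np, 0.0);      // raw backward difference
  std::vector<double> ld_dev_f(np, 0.0);        // filtered deviation from mean
  if (state.containsElementNamed("ld_dev_f")) {
    NumericVector v = state["ld_dev_f"];
    if (v.size() == np) ld_dev_f.assign(v.begin(), v.end());
  }
  std::vector<double> lambda_dot_f(np, 0.0);    // rate fed to tension
  if (state.containsElementNamed("lambda_dot_f")) {
    NumericVector v = state["lambda_dot_f"];
    if (v.size() == np) lambda_dot_f.assign(v.begin(), v.end());
  }
  const double tau_ld = 5.0; // ms, smoothing of the redistribution component

  double beta0_eff = len_on ? landp.beta0 : 0.0;

  // tension scale (h(lambda)-independent part) from current cross-bridge state
  auto update_ta_scale = [&]() {
    for (int i = 0; i < np; ++i) {
      double core = (land[i][4] + 1.0) * land[i][0] + land[i][5] * land[i][1];
      ta_scale[i] = std::max(0.0, landp.tref / landp.rs * core);
    }
  };

  auto record = [&](double tglob, int beat, double t_cycle) {
    if (irec >= nrec) return;
    double p_sa = (circ.v[SA] - circp.v0_sa) / circp.c_sa;
    double p_sv = (circ.v[SV] - circp.v0_sv) / circp.c_sv;
    double p_pa = (circ.v[PA] - circp.v0_pa) / circp.c_pa;
    double p_pv = (circ.v[PV] - circp.v0_pv) / circp.c_pv;
    double a_ra = atrial_act(t_cycle, circp.ra_onset, circp.t_atr_dur, cl);
    double a_la = atrial_act(t_cycle, circp.ra_onset + circp.la_delay, circp.t_atr_dur, cl);
    double p_ra = (circp.e_min_ra + (circp.e_max_ra - circp.e_min_ra) * a_ra) * (circ.v[RA] - circp.v0_ra);
    double p_la = (circp.e_min_la + (circp.e_max_la - circp.e_min_la) * a_la) * (circ.v[LA] - circp.v0_la);
    double tot = 0.0; for (int k = 0; k < 8; ++k) tot += circ.v[k];
    double qm[4];
    for (int k = 0; k < 4; ++k)
      qm[k] = q_n > 0 ? q_acc[k] / q_n : circ.q[k];
    for (int k = 0; k < 4; ++k) q_acc[k] = 0.0;
    q_n = 0;
    double row[NH] = {tglob, (double) beat, p_lv, circ.v[LV], p_rv, circ.v[RV],
                      p_sa, p_sv, p_pa, p_pv, p_ra, p_la,
                      circ.v[RA], circ.v[LA], circ.v[SA], circ.v[SV],
                      circ.v[PA], circ.v[PV],
                      qm[MV], qm[AV], qm[TV], qm[PVV], tot,
                      (double) t_cycle};
    for (int c = 0; c < NH; ++c) hemo(irec, c) = row[c];
    for (int i = 0; i < np; ++i) {
      int r = irec * np + i;
      ptr(r, 0) = tglob; ptr(r, 1) = i + 1; ptr(r, 2) = lambda[i];
      ptr(r, 3) = lambda_dot[i];
      double h = len_on ? length_factor_cpp(lambda[i], landp.beta0) : 1.0;
      ptr(r, 4) = h * ta_scale[i];
      ptr(r, 5) = cells[i][0]; ptr(r, 6) = cells[i][3];
      ptr(r, 7) = (double) beat;
    }
    ++irec;
  };

  // initial equilibrium so the first record is consistent
  update_ta_scale();
  double t_lv_tension = 0.0, t_rv_tension = 0.0;
  {
    // pressures for the initial record only; the committed lambda/areas of
    // a continued state are left untouched
    std::vector<double> a_lv(areas_lv), a_rv(areas_rv), lam_tmp0;
    double ten0;
    p_lv = vent_pressure(circ.v[LV], lv, ta_scale, beta0_eff, passp, lambda,
                         0.0, a_lv, lam_tmp0, ten0);
    p_rv = vent_pressure(circ.v[RV], rv, ta_scale, beta0_eff, passp, lambda,
                         0.0, a_rv, lam_tmp0, ten0);
  }
  record(0.0, 1, 0.0);

  // --- main loop ---
  for (int beat = 0; beat < n_beats; ++beat) {
    for (int step = 0; step < steps_per_beat; ++step) {
      double t_cycle = step * dt_mech;
      double tglob = beat * cl + t_cycle + dt_mech;

      std::vector<double> lambda_prev(lambda);

      // EP + tension substeps over [t_cycle, t_cycle + dt_mech) using the
      // stretch and stretch rate of the previous mechanics step, so the
      // equilibrium below sees current-step tension
      for (int i = 0; i < np; ++i) {
        double* y = cells[i].data();
        double* z = land[i].data();
        for (int k = 0; k < ep_sub; ++k) {
          double ts = t_cycle + k * dt_ep;
          double iext = sac_current(y[0], lambda[i], sacp);
          if (ts >= p_tact[i] && ts < p_tact[i] + stim_dur) iext += stim_amp;
          cell_step_rl(y, cellp, iext, dt_ep);
          if ((k + 1) % ten_every == 0)
            land_step_exp(z, lambda[i], lambda_dot_f[i], y[3], landp, vel_on,
                          len_on, dt_ten);
        }
      }
      update_ta_scale();

      // fixed-point iteration between circulation flows and cavity
      // pressure: the wall equilibrium supplies the pressure and local
      // compliance about which the substeps integrate, re-linearized
      // until the end-of-step pressure is self-consistent
      CircS circ_try;
      double vhat_lv = circ.v[LV], vhat_rv = circ.v[RV];
      const double dv_fd = 0.02; // mL, compliance finite-difference step
      const double eta_dt = eta_wall / dt_mech;
      std::vector<double> lam_tmp;
      double ten_tmp;
      int it = 0;
      CircS circ_for_mean = circ;
      double mean_phat_lv = 0, mean_e_lv = 0, mean_vhat_lv = 0;
      double mean_phat_rv = 0, mean_e_rv = 0, mean_vhat_rv = 0;
      for (; it < 50; ++it) {
        double phat_lv = vent_pressure(vhat_lv, lv, ta_scale, beta0_eff,
                                       passp, lambda_prev, eta_dt,
                                       areas_lv, lam_lv, t_lv_tension);
        std::vector<double> a2(areas_lv);
        double e_lv = (vent_pressure(vhat_lv + dv_fd, lv, ta_scale, beta0_eff,
                                     passp, lambda_prev, eta_dt,
                                     a2, lam_tmp, ten_tmp) - phat_lv) / dv_fd;
        double phat_rv = vent_pressure(vhat_rv, rv, ta_scale, beta0_eff,
                                       passp, lambda_prev, eta_dt,
                                       areas_rv, lam_rv, t_rv_tension);
        a2 = areas_rv;
        double e_rv = (vent_pressure(vhat_rv + dv_fd, rv, ta_scale, beta0_eff,
                                     passp, lambda_prev, eta_dt,
                                     a2, lam_tmp, ten_tmp) - phat_rv) / dv_fd;
        circ_try = circ;
        mean_phat_lv = phat_lv; mean_e_lv = e_lv; mean_vhat_lv = vhat_lv;
        mean_phat_rv = phat_rv; mean_e_rv = e_rv; mean_vhat_rv = vhat_rv;
        circ_advance(circ_try, circp, phat_lv, e_lv, vhat_lv,
                     phat_rv, e_rv, vhat_rv, t_cycle, cl, dt_mech,
                     n_circ_sub);
        double pred_lv = phat_lv + e_lv * (circ_try.v[LV] - vhat_lv);
        double pred_rv = phat_rv + e_rv * (circ_try.v[RV] - vhat_rv);
        std::vector<double> a_lv(areas_lv), a_rv(areas_rv);
        double pn_lv = vent_pressure(circ_try.v[LV], lv, ta_scale, beta0_eff,
                                     passp, lambda_prev, eta_dt, a_lv,
                                     lam_tmp, ten_tmp);
        double pn_rv = vent_pressure(circ_try.v[RV], rv, ta_scale, beta0_eff,
                                     passp, lambda_prev, eta_dt, a_rv,
                                     lam_tmp, ten_tmp);
        double err = std::max(
          std::fabs(pn_lv - pred_lv) / std::max(1.0, std::fabs(pn_lv)),
          std::fabs(pn_rv - pred_rv) / std::max(1.0, std::fabs(pn_rv)));
        if (err < 1e-6) break;
        vhat_lv = circ_try.v[LV];
        vhat_rv = circ_try.v[RV];
      }
      if (it >= 49) fp_converged = false;
      if (it + 1 > max_fp_iters) max_fp_iters = it + 1;
      circ = circ_try;
      {
        double qm[4] = {0, 0, 0, 0};
        CircS tmp = circ_for_mean;
        circ_advance(tmp, circp, mean_phat_lv, mean_e_lv, mean_vhat_lv,
                     mean_phat_rv, mean_e_rv, mean_vhat_rv, t_cycle, cl,
                     dt_mech, n_circ_sub, qm);
        for (int j = 0; j < 4; ++j) q_acc[j] += qm[j];
        q_n += 1;
      }
      // committed equilibrium at the end-of-step volumes
      p_lv = vent_pressure(circ.v[LV], lv, ta_scale, beta0_eff, passp,
                           lambda_prev, eta_dt, areas_lv, lam_lv,
                           t_lv_tension);
      p_rv = vent_pressure(circ.v[RV], rv, ta_scale, beta0_eff, passp,
                           lambda_prev, eta_dt, areas_rv, lam_rv,
                           t_rv_tension);
      for (size_t i = 0; i < lv.idx.size(); ++i) lambda[lv.idx[i]] = lam_lv[i];
      for (size_t i = 0; i < rv.idx.size(); ++i) lambda[rv.idx[i]] = lam_rv[i];
      // backward-difference stretch rate, bounded to the physiological
      // range so that solver-scale area re-distributions cannot inject
      // unbounded distortion into the cross-bridge model
      // The raw backward difference carries the common (cavity-driven)
      // stretch rate plus patch-level redistribution noise whose amplitude
      // scales as 1/dt. The common per-ventricle component passes through
      // unfiltered; the deviation is smoothed and bounded before entering
      // the distortion ODEs.
      const double ld_max = 0.01; // 1/ms
      double af = dt_mech / (tau_ld + dt_mech);
      double mean_ld[2] = {0.0, 0.0};
      int n_v[2] = {0, 0};
      for (int i = 0; i < np; ++i) {
        double ld = (lambda[i] - lambda_prev[i]) / dt_mech;
        if (ld > ld_max) ld = ld_max;
        if (ld < -ld_max) ld = -ld_max;
        lambda_dot[i] = ld;
        int v = p_vent[i];
        mean_ld[v] += ld; n_v[v] += 1;
      }
      for (int v = 0; v < 2; ++v) if (n_v[v]) mean_ld[v] /= n_v[v];
      for (int i = 0; i < np; ++i) {
        double dev = lambda_dot[i] - mean_ld[p_vent[i]];
        ld_dev_f[i] += af * (dev - ld_dev_f[i]);
        lambda_dot_f[i] = mean_ld[p_vent[i]] + ld_dev_f[i];
      }

      if ((step + 1) % rec_stride == 0)
        record(tglob, beat + 1, pmod(t_cycle + dt_mech, cl));
    }
  }

  // --- pack outputs ---
  colnames(hemo) = CharacterVector::create(
    "time_ms", "beat", "p_lv", "v_lv", "p_rv", "v_rv", "p_sa", "p_sv", "p_pa",
    "p_pv", "p_ra", "p_la", "v_ra", "v_la", "v_sa", "v_sv", "v_pa", "v_pv",
    "q_mv", "q_av", "q_tv", "q_pv", "total_volume", "t_cycle");
  colnames(ptr) = CharacterVector::create(
    "time_ms", "patch", "lambda", "lambda_dot", "tension_kpa", "vm_mv",
    "cai_mm", "beat");

  NumericMatrix cells_out(N_CELL_STATE, np), land_out(N_LAND_STATE, np);
  for (int i = 0; i < np; ++i) {
    for (int k = 0; k < N_CELL_STATE; ++k) cells_out(k, i) = cells[i][k];
    for (int k = 0; k < N_LAND_STATE; ++k) land_out(k, i) = land[i][k];
  }
  NumericVector circ_out(12);
  for (int k = 0; k < 8; ++k) circ_out[k] = circ.v[k];
  for (int k = 0; k < 4; ++k) circ_out[8 + k] = circ.q[k];
  circ_out.attr("names") = CharacterVector::create(
    "v_sa", "v_sv", "v_pa", "v_pv", "v_ra", "v_la", "v_lv", "v_rv",
    "q_mv", "q_av", "q_tv", "q_pv");
  NumericVector areas_out(np), lam_out(np);
  for (size_t i = 0; i < lv.idx.size(); ++i) areas_out[lv.idx[i]] = areas_lv[i];
  for (size_t i = 0; i < rv.idx.size(); ++i) areas_out[rv.idx[i]] = areas_rv[i];
  for (int i = 0; i < np; ++i) lam_out[i] = lambda[i];

  NumericVector ldf_out(ld_dev_f.begin(), ld_dev_f.end());
  NumericVector lfd_out(lambda_dot_f.begin(), lambda_dot_f.end());
  List fin = List::create(_["cells"] = cells_out, _["land"] = land_out,
                          _["circ"] = circ_out, _["lambda"] = lam_out,
                          _["areas"] = areas_out, _["p_lv"] = p_lv,
                          _["p_rv"] = p_rv, _["ld_dev_f"] = ldf_out,
                          _["lambda_dot_f"] = lfd_out);
  return List::create(_["hemo"] = hemo, _["patch"] = ptr, _["state"] = fin,
                      _["fp_converged"] = fp_converged,
                      _["max_fp_iterations"] = max_fp_iters);
}
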