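// Cross-bridge active-tension model (Land-type three-state scheme with
// troponin gating, length dependence via h(lambda) and Ca50(lambda), and
// shortening-velocity dependence via the distortion variables).
#include "cardiomef.h"
using namespace Rcpp;

static double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm))
    stop("parameter vector is missing element '%s'", nm);
  return v[nm];
}

LandP land_from_vec(const NumericVector& p) {
  LandP l;
  l.tref = getp(p, "tref"); l.rs = getp(p, "rs"); l.rw = getp(p, "rw");
  l.kuw = getp(p, "kuw"); l.kws = getp(p, "kws");
  l.kwu = getp(p, "kwu"); l.ksu = getp(p, "ksu");
  l.kb = getp(p, "kb"); l.ku = getp(p, "ku");
  l.ktrpn = getp(p, "ktrpn"); l.ntrpn = getp(p, "ntrpn");
  l.ca50ref = getp(p, "ca50ref"); l.ntm = getp(p, "ntm");
  l.trpn50 = getp(p, "trpn50");
  l.gamma_s = getp(p, "gamma_s"); l.gamma_w = getp(p, "gamma_w");
  l.cs = getp(p, "cs"); l.cw = getp(p, "cw"); l.aeff = getp(p, "aeff");
  l.beta0 = getp(p, "beta0"); l.beta1 = getp(p, "beta1");
  return l;
}

// h(lambda) = max(0, h'(min(lambda, 1.2))), h'(x) = 1 + beta0*(x + min(x, 0.87) - 1.87)
double length_factor_cpp(double lambda, double beta0) {
  double x = std::min(lambda, 1.2);
  double hp = 1.0 + beta0 * (x + std::min(x, 0.87) - 1.87);
  return std::max(0.0, hp);
}

double ca50_cpp(double lambda, double beta1, double ca50ref) {
  return ca50ref + beta1 * (std::min(lambda, 1.2) - 1.0);
}

// strain-dependent unbinding rates of the distorted states
static double gamma_su_rate(double zs, double gamma_s) {
  if (zs + 1.0 < 0.0) return gamma_s * (-zs - 1.0);
  if (zs + 1.0 > 1.0) return gamma_s * zs;
  return 0.0;
}
static double gamma_wu_rate(double zw, double gamma_w) {
  return gamma_w * std::fabs(zw);
}

void land_derivs(const double* y, double lambda, double lambda_dot, double cai,
                 const LandP& p, bool vel_on, bool len_on, double* dy) {
  const double S = y[0], W = y[1], catrpn = y[2], B = y[3], zs = y[4], zw = y[5];
  const double aeff = vel_on ? p.aeff : 0.0;
  const double beta1 = len_on ? p.beta1 : 0.0;

  const double U = 1.0 - B - S - W;
  const double gsu = gamma_su_rate(zs, p.gamma_s);
  const double gwu = gamma_wu_rate(zw, p.gamma_w);

  dy[0] = p.kws * W - p.ksu * S - gsu * S;
  dy[1] = p.kuw * U - p.kwu * W - p.kws * W - gwu * W;

  const double ca50 = ca50_cpp(lambda, beta1, p.ca50ref);
  const double ratio = std::pow(cai / ca50, p.ntrpn);
  dy[2] = p.ktrpn * (ratio * (1.0 - catrpn) - catrpn);

  const double ct = std::max(catrpn, 1e-8);
  const double unblock = p.ku * std::pow(ct, p.ntm / 2.0);
  const double block = p.kb * std::min(100.0, std::pow(ct, -p.ntm / 2.0));
  dy[3] = block * U - unblock * B;

  dy[4] = aeff * lambda_dot - p.cs * zs;
  dy[5] = aeff * lambda_dot - p.cw * zw;
}

// Exponential (unconditionally stable) update: each state is linear in itself
// given the others, so an exact one-step exponential integration is used.
void land_step_exp(double* y, double lambda, double lambda_dot, double cai,
                   const LandP& p, bool vel_on, bool len_on, double dt) {
  const double aeff = vel_on ? p.aeff : 0.0;
  const double beta1 = len_on ? p.beta1 : 0.0;

  double S = y[0], W = y[1], catrpn = y[2], B = y[3], zs = y[4], zw = y[5];

  // troponin
  const double ca50 = ca50_cpp(lambda, beta1, p.ca50ref);
  const double ratio = std::pow(cai / ca50, p.ntrpn);
  {
    double rate = p.ktrpn * (ratio + 1.0);
    double inf = ratio / (ratio + 1.0);
    catrpn = inf + (catrpn - inf) * std::exp(-dt * rate);
  }

  // blocked fraction: dB = block*(1 - S - W) - (block + unblock)*B
  const double ct = std::max(catrpn, 1e-8);
  const double unblock = p.ku * std::pow(ct, p.ntm / 2.0);
  const double block = p.kb * std::min(100.0, std::pow(ct, -p.ntm / 2.0));
  {
    double rate = block + unblock;
    double inf = block * (1.0 - S - W) / rate;
    B = inf + (B - inf) * std::exp(-dt * rate);
  }

  // pre-powerstroke: dW = kuw*(1 - B - S) - (kuw + kwu + kws + gwu)*W
  const double gwu = gamma_wu_rate(zw, p.gamma_w);
  {
    double rate = p.kuw + p.kwu + p.kws + gwu;
    double inf = p.kuw * (1.0 - B - S) / rate;
    W = inf + (W - inf) * std::exp(-dt * rate);
  }

  // post-powerstroke: dS = kws*W - (ksu + gsu)*S
  const double gsu = gamma_su_rate(zs, p.gamma_s);
  {
    double rate = p.ksu + gsu;
    double inf = p.kws * W / rate;
    S = inf + (S - inf) * std::exp(-dt * rate);
  }

  // distortions (linear, exact given constant lambda_dot over the step)
  {
    double inf = aeff * lambda_dot / p.cs;
    zs = inf + (zs - inf) * std::exp(-dt * p.cs);
    inf = aeff * lambda_dot / p.cw;
    zw = inf + (zw - inf) * std::exp(-dt * p.cw);
  }

  y[0] = std::min(1.0, std::max(0.0, S));
  y[1] = std::min(1.0, std::max(0.0, W));
  y[2] = std::min(1.0, std::max(0.0, catrpn));
  y[3] = std::min(1.0, std::max(0.0, B));
  y[4] = zs; y[5] = zw;
}

double active_tension_cpp(const double* y, double lambda, const LandP& p,
                          bool len_on) {
  double h = len_on ? length_factor_cpp(lambda, p.beta0) : 1.0;
  double core = (y[4] + 1.0) * y[0] + y[5] * y[1];
  return std::max(0.0, h * p.tref / p.rs * core);
}

// [[Rcpp::export]]
NumericVector cpp_land_derivs(NumericVector state, double lambda,
                              double lambda_dot, double cai,
                              NumericVector params,
                              bool velocity_on, bool length_on) {
  if (state.size() != N_LAND_STATE) stop("tension state must have 6 entries");
  for (int i = 0; i < state.size(); ++i)
    if (!R_finite(state[i])) stop("non-finite tension state component");
  if (!R_finite(lambda) || !R_finite(lambda_dot) || !R_finite(cai))
    stop("non-finite input to land_derivatives");
  LandP p = land_from_vec(params);
  NumericVector out(N_LAND_STATE);
  land_derivs(REAL(state), lambda, lambda_dot, cai, p, velocity_on, length_on,
              REAL(out));
  out.attr("names") = state.attr("names");
  return out;
}

// [[Rcpp::export]]
double cpp_active_tension(NumericVector state, double lambda,
                          NumericVector params, bool length_on) {
  if (state.size() != N_LAND_STATE) stop("tension state must have 6 entries");
  LandP p = land_from_vec(params);
  return active_tension_cpp(REAL(state), lambda, p, length_on);
}

// Integrate the tension model against prescribed calcium and stretch series
// (sampled every dt); returns the tension trace and final state.
// [[Rcpp::export]]
List cpp_run_land(NumericVector state, NumericVector params,
                  NumericVector cai_t, NumericVector lambda_t,
                  NumericVector lambda_dot_t, double dt,
                  bool velocity_on, bool length_on) {
  if (state.size() != N_LAND_STATE) stop("tension state must have 6 entries");
  LandP p = land_from_vec(params);
  int n = cai_t.size();
  if (lambda_t.size() != n || lambda_dot_t.size() != n)
    stop("calcium and stretch series must have equal length");

  NumericVector ta(n);
  std::vector<double> y(REAL(state), REAL(state) + N_LAND_STATE);
  for (int i = 0; i < n; ++i) {
    ta[i] = active_tension_cpp(y.data(), lambda_t[i], p, length_on);
    land_step_exp(y.data(), lambda_t[i], lambda_dot_t[i], cai_t[i], p,
                  velocity_on, length_on, dt);
  }
  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = state.attr("names");
  return List::create(_["tension"] = ta, _["state"] = fin);
}
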