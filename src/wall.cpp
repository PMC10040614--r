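// Passive fiber stress from an orthotropic exponential strain energy reduced
// to the fiber axis under incompressible uniaxial kinematics, and the
// multi-patch thin-wall equilibrium solve (common membrane tension, areas
// summing to the midwall sphere area).
#include "cardiomef.h"
using namespace Rcpp;

static double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm))
    stop("parameter vector is missing element '%s'", nm);
  return v[nm];
}

PassP pass_from_vec(const NumericVector& p) {
  PassP pp;
  pp.c = getp(p, "c_mat"); pp.bff = getp(p, "bff");
  pp.bss = getp(p, "bss"); pp.bnn = getp(p, "bnn");
  return pp;
}

// Along the uniaxial incompressible path: Eff = (lambda^2 - 1)/2,
// Ess = Enn = (1/lambda - 1)/2, shears zero.  Cauchy fiber stress with the
// transverse normal stress eliminated is lambda * dPsi/dlambda (J = 1).
double passive_stress_cpp(double lambda, const PassP& p) {
  double eff = 0.5 * (lambda * lambda - 1.0);
  double et = 0.5 * (1.0 / lambda - 1.0);
  double q = p.bff * eff * eff + (p.bss + p.bnn) * et * et;
  double dq = 2.0 * p.bff * eff * lambda - (p.bss + p.bnn) * et / (lambda * lambda);
  return lambda * 0.5 * p.c * std::exp(q) * dq;
}

double passive_stress_deriv_cpp(double lambda, const PassP& p) {
  double eff = 0.5 * (lambda * lambda - 1.0);
  double et = 0.5 * (1.0 / lambda - 1.0);
  double q = p.bff * eff * eff + (p.bss + p.bnn) * et * et;
  double dq = 2.0 * p.bff * eff * lambda - (p.bss + p.bnn) * et / (lambda * lambda);
  double l2 = lambda * lambda;
  double d2q = 2.0 * p.bff * (eff + l2) +
               (p.bss + p.bnn) * (0.5 / (l2 * l2) + 2.0 * et / (l2 * lambda));
  double eq = std::exp(q);
  return 0.5 * p.c * eq * dq + lambda * 0.5 * p.c * eq * (dq * dq + d2q);
}

// dh'/dlambda of the length factor (0 where clamped or floored)
static double length_factor_deriv(double lambda, double beta0) {
  if (lambda >= 1.2) return 0.0;
  double x = lambda;
  double hp = 1.0 + beta0 * (x + std::min(x, 0.87) - 1.87);
  if (hp <= 0.0) return 0.0;
  return (x < 0.87) ? 2.0 * beta0 : beta0;
}

// membrane tension of patch i at area a: T = sigma(lambda) * vwall / a,
// lambda = sqrt(a / aref)
static void patch_tension(double a, double aref, double vwall, double ta_scale,
                          double beta0_eff, const PassP& pp,
                          double lam_prev, double eta_dt,
                          double* t_out, double* dtda_out) {
  double lam = std::sqrt(a / aref);
  double sig = passive_stress_cpp(lam, pp) +
               length_factor_cpp(lam, beta0_eff) * ta_scale +
               eta_dt * (lam - lam_prev);
  double dsig = passive_stress_deriv_cpp(lam, pp) +
                length_factor_deriv(lam, beta0_eff) * ta_scale + eta_dt;
  double t = sig * vwall / a;
  double dlam_da = lam / (2.0 * a);
  double dt = dsig * dlam_da * vwall / a - sig * vwall / (a * a);
  *t_out = t;
  *dtda_out = dt;
}

int patch_equilibrium_solve(const std::vector<double>& aref,
                            const std::vector<double>& vwall,
                            const std::vector<double>& ta_scale,
                            double beta0_eff, const PassP& pp,
                            double a_mid,
                            const std::vector<double>& lam_prev,
                            double eta_dt,
                            std::vector<double>& areas,
                            double& tension) {
  const int n = (int) aref.size();
  const int maxit = 50;
  const double lam_lo = 0.55, lam_hi = 1.95;

  std::vector<double> t(n), dt(n), r(n), anew(n);

  // initialize / repair warm start
  double asum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!(areas[i] > 0.0)) areas[i] = aref[i];
    asum += areas[i];
  }
  for (int i = 0; i < n; ++i) areas[i] *= a_mid / asum;

  double tbar = 0.0;
  for (int it = 0; it < maxit; ++it) {
    tbar = 0.0;
    for (int i = 0; i < n; ++i) {
      double lp = lam_prev.empty() ? 1.0 : lam_prev[i];
      patch_tension(areas[i], aref[i], vwall[i], ta_scale[i], beta0_eff, pp,
                    lp, eta_dt, &t[i], &dt[i]);
      tbar += t[i];
    }
    tbar /= n;

    // convergence: tension equalized (mixed abs/rel) -- areas sum to a_mid
    // exactly by construction of the update below
    double scale = std::max(std::fabs(tbar), 1e-3); // kPa*cm floor near zero
    double worst = 0.0;
    for (int i = 0; i < n; ++i)
      worst = std::max(worst, std::fabs(t[i] - tbar) / scale);
    if (worst < 1e-10) { tension = tbar; return it; }

    // Newton step with arrow elimination; clamp non-positive slopes so the
    // iteration remains a descent even on the active-tension plateau
    double jmin = 0.0;
    for (int i = 0; i < n; ++i) jmin = std::max(jmin, std::fabs(dt[i]));
    jmin = std::max(1e-12, 1e-6 * jmin);
    double sum_inv = 0.0, sum_rj = 0.0;
    for (int i = 0; i < n; ++i) {
      double j = dt[i] > jmin ? dt[i] : jmin;
      sum_inv += 1.0 / j;
      sum_rj += t[i] / j;
    }
    // common tension solving sum_i dA_i = 0 with dA_i = (T - t_i)/J_i
    double tstar = sum_rj / sum_inv;

    double step = 1.0;
    for (int tries = 0; tries < 30; ++tries) {
      double tot = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        double j = dt[i] > jmin ? dt[i] : jmin;
        double da = step * (tstar - t[i]) / j;
        double amax = aref[i] * lam_hi * lam_hi;
        double amin = aref[i] * lam_lo * lam_lo;
        anew[i] = std::min(amax, std::max(amin, areas[i] + da));
        tot += anew[i];
        if (!R_finite(anew[i])) ok = false;
      }
      if (ok && tot > 0.0) {
        // renormalize to conserve total area exactly
        double f = a_mid / tot;
        if (f > 0.5 && f < 2.0) {
          for (int i = 0; i < n; ++i) anew[i] *= f;
          break;
        }
      }
      step *= 0.5;
    }
    areas = anew;
  }

  // report final (possibly unconverged) tension; caller decides
  tbar = 0.0;
  for (int i = 0; i < n; ++i) {
    double lp = lam_prev.empty() ? 1.0 : lam_prev[i];
    patch_tension(areas[i], aref[i], vwall[i], ta_scale[i], beta0_eff, pp,
                  lp, eta_dt, &t[i], &dt[i]);
    tbar += t[i];
  }
  tension = tbar / n;
  double scale = std::max(std::fabs(tension), 1e-3);
  double worst = 0.0;
  for (int i = 0; i < n; ++i)
    worst = std::max(worst, std::fabs(t[i] - tension) / scale);
  return worst < 1e-8 ? maxit : -1;
}

// [[Rcpp::export]]
double cpp_passive_stress(double lambda, NumericVector params) {
  if (lambda <= 0.5 || lambda >= 2.0)
    stop("lambda must lie in (0.5, 2)");
  return passive_stress_cpp(lambda, pass_from_vec(params));
}

// [[Rcpp::export]]
double cpp_passive_stress_deriv(double lambda, NumericVector params) {
  return passive_stress_deriv_cpp(lambda, pass_from_vec(params));
}

// [[Rcpp::export]]
List cpp_patch_equilibrium(NumericVector aref, NumericVector vwall,
                           NumericVector ta_scale, double beta0_eff,
                           NumericVector passive, double a_mid,
                           NumericVector warm_areas) {
  int n = aref.size();
  if (vwall.size() != n || ta_scale.size() != n)
    stop("aref, vwall and ta_scale must have equal length");
  PassP pp = pass_from_vec(passive);
  std::vector<double> areas(n);
  if (warm_areas.size() == n)
    for (int i = 0; i < n; ++i) areas[i] = warm_areas[i];
  else
    for (int i = 0; i < n; ++i) areas[i] = aref[i];

  std::vector<double> ar(aref.begin(), aref.end());
  std::vector<double> vw(vwall.begin(), vwall.end());
  std::vector<double> ts(ta_scale.begin(), ta_scale.end());
  double tension = 0.0;
  std::vector<double> no_prev;
  int it = patch_equilibrium_solve(ar, vw, ts, beta0_eff, pp, a_mid, no_prev,
                                   0.0, areas, tension);
  if (it < 0)
    stop("patch equilibrium solve did not converge within 50 iterations");

  NumericVector a(areas.begin(), areas.end());
  NumericVector lam(n);
  for (int i = 0; i < n; ++i) lam[i] = std::sqrt(areas[i] / aref[i]);
  return List::create(_["areas"] = a, _["lambda"] = lam,
                      _["tension"] = tension, _["iterations"] = it);
}
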