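#ifndef CARDIOMEF_H
#define CARDIOMEF_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// ---- ionic myocyte model (human ventricular, epi/endo/mid variants) ----
// State layout (19 entries), shared between C++ and R:
//  0 V    (mV)      6 m     12 fcass
//  1 Nai  (mM)      7 h     13 r
//  2 Ki   (mM)      8 j     14 s
//  3 Cai  (mM)      9 d     15 xr1
//  4 CaSS (mM)     10 f     16 xr2
//  5 CaSR (mM)     11 f2    17 xs
//                           18 rbar (ryanodine-receptor availability)
#define N_CELL_STATE 19

struct CellP {
  int    cell_type;   // 0 epi, 1 endo, 2 mid (affects s-gate kinetics)
  double g_na, g_k1, g_kr, g_ks, g_to, g_cal;
  double g_bna, g_bca, g_pca, g_pk;
  double p_nak, k_naca;
  double cm;          // uF/cm^2, scales current->concentration conversion
};

struct SacP {
  double g;      // A/F per mV (maximal stretch-activated conductance)
  double e_rev;  // mV
  double k_sig;  // sigmoid scaling
  double alpha;  // sigmoid steepness per unit stretch
  int    enabled;
};

CellP cell_from_vec(const Rcpp::NumericVector& p);
SacP  sac_from_vec(const Rcpp::NumericVector& p);

void cell_derivs(const double* y, const CellP& p, double i_ext, double* dy);
void cell_step_rl(double* y, const CellP& p, double i_ext, double dt);
double sac_current(double vm, double lambda, const SacP& s);

// ---- cross-bridge active-tension model ----
// State layout (6): 0 S, 1 W, 2 CaTRPN, 3 B, 4 zeta_s, 5 zeta_w
#define N_LAND_STATE 6

struct LandP {
  double tref, rs, rw;
  double kuw, kws, kwu, ksu, kb, ku;
  double ktrpn, ntrpn, ca50ref, ntm, trpn50;
  double gamma_s, gamma_w;
  double cs, cw, aeff;
  double beta0, beta1;
};

LandP land_from_vec(const Rcpp::NumericVector& p);
double length_factor_cpp(double lambda, double beta0);
double ca50_cpp(double lambda, double beta1, double ca50ref);
void land_derivs(const double* y, double lambda, double lambda_dot, double cai,
                 const LandP& p, bool vel_on, bool len_on, double* dy);
void land_step_exp(double* y, double lambda, double lambda_dot, double cai,
                   const LandP& p, bool vel_on, bool len_on, double dt);
double active_tension_cpp(const double* y, double lambda, const LandP& p,
                          bool len_on);

// ---- passive wall material (orthotropic energy reduced to the fiber axis) ----
struct PassP { double c, bff, bss, bnn; };
PassP pass_from_vec(const Rcpp::NumericVector& p);
double passive_stress_cpp(double lambda, const PassP& p);
double passive_stress_deriv_cpp(double lambda, const PassP& p);

// ---- multi-patch thin-wall equilibrium ----
// Solves for patch areas with common membrane tension at prescribed cavity
// volume; returns iterations used (<0 on failure).
// lam_prev/eta_dt add a per-patch viscous stress eta * (lambda - lambda_prev) / dt
// (pass empty lam_prev or eta_dt = 0 for the static problem)
int patch_equilibrium_solve(const std::vector<double>& aref,
                            const std::vector<double>& vwall,
                            const std::vector<double>& ta_scale, // kPa, h(lambda)-free part
                            double beta0_eff,
                            const PassP& pp,
                            double a_mid,              // total midwall area (cm^2)
                            const std::vector<double>& lam_prev,
                            double eta_dt,             // kPa per unit stretch rate*dt
                            std::vector<double>& areas, // in: warm start, out: solution
                            double& tension);           // out: common tension kPa*cm

#endif
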