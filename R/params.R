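#' Ventricular myocyte parameters
#'
#' Channel conductances and kinetic selection for the human ventricular
#' myocyte model. The three transmural cell types of the published model are
#' provided as presets; every conductance can be overridden.
#'
#' @param cell_type one of `"epi"`, `"endo"`, `"mid"`. The preset changes the
#'   transient-outward and slow-delayed-rectifier conductances and the
#'   inactivation kinetics of the transient-outward current.
#' @param ... named overrides for individual entries (e.g. `g_na = 10`).
#' @return a named numeric vector of class `cardiomef_cell_params`.
#' @export
#' @examples
#' cell_params("epi")["g_to"]
cell_params <- function(cell_type = c("epi", "endo", "mid"), ...) {
  cell_type <- match.arg(cell_type)
  type_code <- c(epi = 0, endo = 1, mid = 2)[[cell_type]]
  p <- c(
    cell_type = type_code,
    g_na = 14.838, g_k1 = 5.405, g_kr = 0.153,
    g_ks = if (cell_type == "mid") 0.098 else 0.392,
    g_to = if (cell_type == "endo") 0.073 else 0.294,
    g_cal = 3.980e-5, g_bna = 0.00029, g_bca = 0.000592,
    g_pca = 0.1238, g_pk = 0.0146, p_nak = 2.724, k_naca = 1000,
    cm = 0.185
  )
  p <- apply_overrides(p, list(...), protect = "cell_type")
  conds <- setdiff(names(p), c("cell_type", "cm"))
  if (any(p[conds] < 0)) abort("channel conductances must be non-negative")
  if (p[["cm"]] <= 0) abort("membrane capacitance must be positive")
  structure(p, class = c("cardiomef_cell_params", "numeric"))
}

#' Initial (resting) myocyte state
#'
#' The published initial conditions of the ionic model: a hyperpolarized
#' resting membrane, closed gates and low cytosolic calcium. Pacing to a
#' periodic steady state should start from here (see
#' [pace_to_steady_state()]).
#'
#' @return a named numeric vector with 19 entries (membrane potential in mV,
#'   concentrations in mM, gates dimensionless).
#' @export
cell_state <- function() {
  c(V = -86.2, Nai = 7.67, Ki = 138.3, Cai = 7e-5, CaSS = 7e-5, CaSR = 1.3,
    m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1, fcass = 1, r = 0, s = 1,
    xr1 = 0, xr2 = 1, xs = 0, rbar = 1)
}

#' Stretch-activated channel parameters
#'
#' Sigmoidal stretch-gated, weakly selective cation current
#' `I = G (Vm - E) / (1 + K exp(-alpha (lambda - 1)))`. The default maximal
#' conductance is the package's calibrated value for a 10% trigger level
#' (see [calibrate_sac()]); reversal potential and sigmoid shape follow the
#' published channel formulation.
#'
#' @param g maximal conductance (A/F per mV).
#' @param e_rev reversal potential (mV).
#' @param k_sig sigmoid scaling factor (dimensionless).
#' @param alpha sigmoid steepness (per unit stretch).
#' @param enabled logical; a disabled channel carries zero current.
#' @return named numeric vector of class `cardiomef_sac_params`.
#' @export
sac_params <- function(g = 0.2182, e_rev = -20, k_sig = 100, alpha = 30,
                       enabled = TRUE) {
  if (g < 0) abort("SAC conductance must be non-negative")
  if (k_sig <= 0 || alpha <= 0) abort("K and alpha must be positive")
  structure(c(g = g, e_rev = e_rev, k_sig = k_sig, alpha = alpha,
              enabled = as.numeric(enabled)),
            class = c("cardiomef_sac_params", "numeric"))
}

#' Active-tension (cross-bridge) model parameters
#'
#' Three-state cross-bridge scheme with troponin gating, distortion
#' (velocity) dependence and length dependence. Defaults are the cited human
#' formulation of the model; `tref` here carries the package's organ-level
#' calibration for the canine-sized surrogate.
#'
#' The derived rates `kwu`, `ksu`, `kb`, `cs`, `cw` are computed from the
#' primary parameters unless given explicitly.
#'
#' @param tref maximal active tension at resting length (kPa).
#' @param rs,rw steady-state duty ratios of the post- and pre-powerstroke
#'   states.
#' @param kuw,kws forward transition rates (1/ms).
#' @param ku troponin unblocking rate scale (1/ms).
#' @param ktrpn calcium-troponin binding rate (1/ms).
#' @param ntrpn binding cooperativity.
#' @param ca50ref half-activation calcium at resting length (mM).
#' @param ntm tropomyosin cooperativity.
#' @param trpn50 troponin occupancy at half tropomyosin activation.
#' @param gamma_s,gamma_w distortion-dependent unbinding rate scales (1/ms).
#' @param phi distortion decay scaling linking `cs`, `cw` to the cycling
#'   rates.
#' @param aeff velocity-dependence coefficient (dimensionless gain on the
#'   stretch rate).
#' @param beta0 length dependence of maximal tension (dimensionless).
#' @param beta1 length dependence of calcium sensitivity (mM per unit
#'   stretch); negative values sensitise the myofilaments with stretch, as
#'   in the cited formulation.
#' @param ... explicit overrides for the derived rates (`kwu`, `ksu`, `kb`,
#'   `cs`, `cw`).
#' @return named numeric vector of class `cardiomef_land_params`.
#' @export
land_params <- function(tref = 160, rs = 0.25, rw = 0.5,
                        kuw = 0.182, kws = 0.012, ku = 0.15,
                        ktrpn = 0.1, ntrpn = 2, ca50ref = 0.00115,
                        ntm = 3.5, trpn50 = 0.35,
                        gamma_s = 0.0085, gamma_w = 0.615, phi = 2.23,
                        aeff = 25, beta0 = 2.3, beta1 = -0.0024, ...) {
  if (any(c(tref, rs, rw, kuw, kws, ku, ktrpn) <= 0))
    abort("tref, duty ratios and rates must be positive")
  if (ntrpn < 1) abort("ntrpn must be >= 1")
  if (aeff < 0) abort("aeff must be non-negative")
  derived <- list(
    kwu = kuw * (1 / rw - 1) - kws,
    ksu = kws * rw * (1 / rs - 1),
    kb = ku * trpn50^ntm / (1 - rs - (1 - rs) * rw),
    cs = phi * kws * rw * (1 - rs) / rs,
    cw = phi * kuw
  )
  dots <- list(...)
  for (nm in intersect(names(dots), names(derived))) derived[[nm]] <- dots[[nm]]
  extra <- setdiff(names(dots), names(derived))
  if (length(extra)) abort(paste("unknown tension parameter:", extra[1]))
  p <- c(tref = tref, rs = rs, rw = rw, kuw = kuw, kws = kws, ku = ku,
         ktrpn = ktrpn, ntrpn = ntrpn, ca50ref = ca50ref, ntm = ntm,
         trpn50 = trpn50, gamma_s = gamma_s, gamma_w = gamma_w,
         aeff = aeff, beta0 = beta0, beta1 = beta1,
         kwu = derived$kwu, ksu = derived$ksu, kb = derived$kb,
         cs = derived$cs, cw = derived$cw)
  if (p[["cs"]] <= 0 || p[["cw"]] <= 0) abort("distortion decay rates must be positive")
  structure(p, class = c("cardiomef_land_params", "numeric"))
}

#' Resting cross-bridge state
#'
#' Equilibrium of the tension model at a given diastolic calcium and resting
#' length: troponin occupancy at its steady value, tropomyosin mostly
#' blocked, no attached cross-bridges and no distortion.
#'
#' @param params tension parameters from [land_params()].
#' @param cai_diastolic diastolic calcium (mM).
#' @return named numeric vector with entries `S, W, CaTRPN, B, zeta_s,
#'   zeta_w`.
#' @export
land_state <- function(params = land_params(), cai_diastolic = 1.3e-4) {
  y <- c(S = 0, W = 0, CaTRPN = 0.01, B = 1, zeta_s = 0, zeta_w = 0)
  # relax to equilibrium against constant calcium at resting length
  n <- 5000
  out <- cpp_run_land(y, params, rep(cai_diastolic, n), rep(1, n), rep(0, n),
                      dt = 1, velocity_on = TRUE, length_on = TRUE)
  out$state
}

#' Passive myocardial material parameters
#'
#' Orthotropic exponential strain-energy material reduced to the fiber axis.
#' Exponent coefficients follow the cited orthotropic formulation; the
#' scaling `c_mat` carries the package's canine-surrogate calibration.
#'
#' @param c_mat material scaling (kPa).
#' @param bff,bss,bnn axial exponent coefficients (fiber, sheet, normal).
#' @param bfs,bfn,bsn shear exponent coefficients (unused in the fiber-axis
#'   reduction where shears vanish; kept for completeness).
#' @param k_incomp incompressibility factor (kPa); inactive in the
#'   isochoric uniaxial reduction.
#' @param eta myocardial viscosity (kPa ms): a stress `eta * dlambda/dt`
#'   added to the wall material inside the coupled simulation, giving the
#'   wall its physiological viscoelastic damping.
#' @return named numeric vector of class `cardiomef_passive_params`.
#' @export
passive_params <- function(c_mat = 8.8, bff = 8, bss = 6, bnn = 3,
                           bfs = 12, bfn = 3, bsn = 3, k_incomp = 100,
                           eta = 1000) {
  if (c_mat <= 0) abort("material scaling must be positive")
  if (any(c(bff, bss, bnn, bfs, bfn, bsn) < 0))
    abort("exponent coefficients must be non-negative")
  if (k_incomp <= 0) abort("incompressibility factor must be positive")
  if (eta < 0) abort("viscosity must be non-negative")
  structure(c(c_mat = c_mat, bff = bff, bss = bss, bnn = bnn, bfs = bfs,
              bfn = bfn, bsn = bsn, k_incomp = k_incomp, eta = eta),
            class = c("cardiomef_passive_params", "numeric"))
}

#' Mechanoelectric feedback toggles
#'
#' Switches for the three MEF mechanisms: velocity dependence of active
#' tension (distortion gain), length dependence (`h(lambda)` and the
#' stretch-sensitive calcium affinity), and the stretch-activated current.
#'
#' @param velocity_dependence,length_dependence,sac_enabled logicals.
#' @return named numeric vector of class `cardiomef_toggles`.
#' @export
mef_toggles <- function(velocity_dependence = TRUE, length_dependence = TRUE,
                        sac_enabled = TRUE) {
  structure(c(velocity_dependence = as.numeric(velocity_dependence),
              length_dependence = as.numeric(length_dependence),
              sac_enabled = as.numeric(sac_enabled)),
            class = c("cardiomef_toggles", "numeric"))
}

apply_overrides <- function(p, dots, protect = character()) {
  if (!length(dots)) return(p)
  bad <- setdiff(names(dots), setdiff(names(p), protect))
  if (length(bad)) abort(paste("unknown parameter:", bad[1]))
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}
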