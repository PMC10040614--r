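#' Length-dependence factor of active tension
#'
#' `h(lambda) = max(0, h'(min(lambda, 1.2)))` with
#' `h'(x) = 1 + beta0 (x + min(x, 0.87) - 1.87)`: unity at resting length,
#' increasing with stretch up to the 1.2 clamp, floored at zero for strong
#' shortening. Vectorised over `lambda`.
#'
#' @param lambda stretch ratio (> 0).
#' @param beta0 length-dependence coefficient.
#' @return dimensionless factor.
#' @export
#' @examples
#' length_factor(1.1, beta0 = 2) # 1.2
length_factor <- function(lambda, beta0) {
  if (any(lambda <= 0)) abort("lambda must be positive")
  x <- pmin(lambda, 1.2)
  pmax(0, 1 + beta0 * (x + pmin(x, 0.87) - 1.87))
}

#' Stretch-dependent calcium sensitivity
#'
#' Half-activation calcium of the troponin binding,
#' `Ca50 = Ca50_ref + beta1 (min(lambda, 1.2) - 1)`.
#'
#' @inheritParams length_factor
#' @param beta1 length dependence of the calcium sensitivity (mM per unit
#'   stretch).
#' @param ca50_ref half-activation calcium at resting length (mM).
#' @return Ca50 (mM).
#' @export
ca50 <- function(lambda, beta1, ca50_ref) {
  if (any(lambda <= 0)) abort("lambda must be positive")
  ca50_ref + beta1 * (pmin(lambda, 1.2) - 1)
}

#' Time derivative of the cross-bridge state
#'
#' The six ODEs of the tension model: cross-bridge fractions `S`, `W`,
#' tropomyosin blocking `B`, troponin occupancy `CaTRPN`, and the
#' distortions `zeta_s`, `zeta_w` driven by the stretch rate. With velocity
#' dependence toggled off the distortion gain is zero; with length
#' dependence off `beta1` is treated as zero.
#'
#' @param state named vector from [land_state()].
#' @param lambda,lambda_dot stretch ratio and its rate (1/ms).
#' @param cai intracellular calcium (mM, > 0).
#' @param params parameters from [land_params()].
#' @param toggles switches from [mef_toggles()].
#' @return named derivative vector.
#' @export
land_derivatives <- function(state, lambda, lambda_dot, cai,
                             params = land_params(), toggles = mef_toggles()) {
  if (cai <= 0) abort("cai must be positive")
  cpp_land_derivs(state, lambda, lambda_dot, cai, params,
                  toggles[["velocity_dependence"]] != 0,
                  toggles[["length_dependence"]] != 0)
}

#' Active tension from the cross-bridge state
#'
#' `Ta = h(lambda) * Tref / rs * ((zeta_s + 1) S + zeta_w W)`, floored at
#' zero. With length dependence off, `h` is identically one.
#'
#' @inheritParams land_derivatives
#' @return tension (kPa).
#' @export
active_tension <- function(state, lambda, params = land_params(),
                           toggles = mef_toggles()) {
  cpp_active_tension(state, lambda, params,
                     toggles[["length_dependence"]] != 0)
}

#' Isometric twitch against a prescribed calcium transient
#'
#' Integrates the tension model for one cycle at fixed stretch (zero
#' stretch rate) and returns the tension trace with its peak and
#' time-to-peak.
#'
#' @param params parameters from [land_params()].
#' @param toggles switches from [mef_toggles()].
#' @param calcium a tibble from [make_calcium()] (columns `time_ms`,
#'   `cai_mm`).
#' @param lambda fixed stretch ratio.
#' @param state initial cross-bridge state; defaults to equilibrium at the
#'   transient's first sample.
#' @param dt integration step (ms); must match the calcium sampling.
#' @return a list: `trace` (tibble `time_ms`, `tension_kpa`), `peak` (kPa),
#'   `time_to_peak` (ms), `state` (final).
#' @export
isometric_twitch <- function(params = land_params(), toggles = mef_toggles(),
                             calcium = make_calcium(), lambda = 1,
                             state = NULL, dt = NULL) {
  stopifnot(is.data.frame(calcium), all(c("time_ms", "cai_mm") %in% names(calcium)))
  if (is.null(dt)) dt <- diff(calcium$time_ms[1:2])
  if (is.null(state)) state <- land_state(params, calcium$cai_mm[1])
  n <- nrow(calcium)
  out <- cpp_run_land(state, params, calcium$cai_mm, rep(lambda, n),
                      rep(0, n), dt,
                      toggles[["velocity_dependence"]] != 0,
                      toggles[["length_dependence"]] != 0)
  trace <- tibble(time_ms = calcium$time_ms, tension_kpa = out$tension)
  ipk <- which.max(trace$tension_kpa)
  list(trace = trace, peak = trace$tension_kpa[ipk],
       time_to_peak = trace$time_ms[ipk], state = out$state)
}
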