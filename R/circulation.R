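#' Lumped circulation parameters
#'
#' Reduced closed-loop circulation: four linear-compliance vascular beds
#' (systemic/pulmonary arteries and veins), two time-varying-elastance
#' atria and four valves with inertance and a smooth diode law. Defaults
#' carry the package's calibration to canine end-diastolic volumes and
#' pressures at 100 beats per minute.
#'
#' @param ... named overrides for individual entries.
#' @return named numeric vector of class `cardiomef_circ_params`.
#' @details Units: compliances mL/mmHg, resistances mmHg ms/mL, Bernoulli
#'   valve resistances mmHg ms^2/mL^2, inertances mmHg ms^2/mL, elastances
#'   mmHg/mL, volumes mL, times ms.
#' @export
circ_params <- function(...) {
  p <- c(
    # vascular compliances and unstressed volumes
    c_sa = 0.8, c_sv = 12, c_pa = 2.2, c_pv = 7,
    v0_sa = 45, v0_sv = 120, v0_pa = 25, v0_pv = 45,
    # bed resistances
    r_sys = 3380, r_sv = 35, r_pul = 450, r_pv = 60,
    # atria (time-varying elastance)
    e_min_ra = 0.06, e_max_ra = 0.38, v0_ra = 5,
    e_min_la = 0.15, e_max_la = 0.18, v0_la = 8,
    t_atr_dur = 150, ra_onset = 0, la_delay = 40,
    # valves: mitral, aortic, tricuspid, pulmonary
    mv_ropen = 15, mv_rclosed = 1e10, mv_inert = 3, mv_rlin = 4,
    av_ropen = 25, av_rclosed = 1e10, av_inert = 5, av_rlin = 10,
    tv_ropen = 15, tv_rclosed = 1e10, tv_inert = 3, tv_rlin = 4,
    pv_ropen = 25, pv_rclosed = 1e10, pv_inert = 5, pv_rlin = 10
  )
  p <- apply_overrides(p, list(...))
  if (any(p[c("c_sa", "c_sv", "c_pa", "c_pv", "r_sys", "r_sv", "r_pul", "r_pv")] <= 0))
    abort("compliances and resistances must be positive")
  for (v in c("mv", "av", "tv", "pv"))
    if (p[[paste0(v, "_rclosed")]] <= p[[paste0(v, "_ropen")]])
      abort("closed valve resistance must exceed open resistance")
  structure(p, class = c("cardiomef_circ_params", "numeric"))
}

#' Valve flow derivative (diode with inertia)
#'
#' `dq/dt = (dP - R_eff q |q| - R_lin q) / L`: a two-term orifice law
#' (turbulent plus laminar resistance) with the effective Bernoulli
#' resistance blending smoothly between the open and closed values
#' according to the flow direction and driving pressure.
#'
#' @param q valve flow (mL/ms).
#' @param dp pressure gradient across the valve (mmHg).
#' @param r_open,r_closed Bernoulli resistances (mmHg ms^2/mL^2).
#' @param r_lin laminar resistance component (mmHg ms/mL).
#' @param inertance blood inertance (mmHg ms^2/mL).
#' @param width blending window on the driving term (mmHg).
#' @return dq/dt (mL/ms^2).
#' @export
valve_flow_derivative <- function(q, dp, r_open, r_closed, inertance,
                                  r_lin = 0, width = 0.01) {
  w <- 1 / (1 + exp(-(dp + q) / width))
  r_eff <- w * r_open + (1 - w) * r_closed
  (dp - r_eff * q * abs(q) - r_lin * q) / inertance
}

#' Atrial pressure from time-varying elastance
#'
#' `P = E(t) (V - V_unstressed)` with a smooth single-peak activation
#' (raised cosine of duration `t_atr_dur`), periodic with the cycle length.
#' The left atrium follows the right after the inter-atrial delay.
#'
#' @param v_atrium atrial volume (mL).
#' @param t time since the start of the cycle (ms).
#' @param params circulation parameters from [circ_params()].
#' @param side `"ra"` or `"la"`.
#' @param cycle_length cycle length (ms).
#' @return pressure (mmHg).
#' @export
atrial_pressure <- function(v_atrium, t, params = circ_params(),
                            side = c("ra", "la"), cycle_length = 600) {
  if (any(v_atrium <= 0)) abort("atrial volume must be positive")
  side <- match.arg(side)
  onset <- params[["ra_onset"]] + if (side == "la") params[["la_delay"]] else 0
  dur <- params[["t_atr_dur"]]
  ph <- (t - onset) %% cycle_length
  a <- ifelse(ph < dur, 0.5 * (1 - cos(2 * pi * ph / dur)), 0)
  emin <- params[[paste0("e_min_", side)]]
  emax <- params[[paste0("e_max_", side)]]
  v0 <- params[[paste0("v0_", side)]]
  (emin + (emax - emin) * a) * (v_atrium - v0)
}

#' Circulation state derivative
#'
#' Volume ODEs as signed sums of adjacent flows, with vascular pressures
#' from linear compliances, atrial pressures from the elastance curves and
#' valve flows following the diode-with-inertia law. The ventricular
#' pressures are inputs (in the coupled model they come from the wall
#' equilibrium). The sum of all volume derivatives is exactly zero.
#'
#' @param state named vector: volumes `v_sa, v_sv, v_pa, v_pv, v_ra, v_la,
#'   v_lv, v_rv` (mL) and valve flows `q_mv, q_av, q_tv, q_pv` (mL/ms).
#' @param t time since the start of the cycle (ms).
#' @param p_lv,p_rv ventricular pressures (mmHg).
#' @param params circulation parameters.
#' @param cycle_length cycle length (ms).
#' @return named derivative vector.
#' @export
circulation_derivatives <- function(state, t, p_lv, p_rv,
                                    params = circ_params(),
                                    cycle_length = 600) {
  s <- as.list(state)
  p_sa <- (s$v_sa - params[["v0_sa"]]) / params[["c_sa"]]
  p_sv <- (s$v_sv - params[["v0_sv"]]) / params[["c_sv"]]
  p_pa <- (s$v_pa - params[["v0_pa"]]) / params[["c_pa"]]
  p_pv <- (s$v_pv - params[["v0_pv"]]) / params[["c_pv"]]
  p_ra <- atrial_pressure(s$v_ra, t, params, "ra", cycle_length)
  p_la <- atrial_pressure(s$v_la, t, params, "la", cycle_length)

  q_sys <- (p_sa - p_sv) / params[["r_sys"]]
  q_sv <- (p_sv - p_ra) / params[["r_sv"]]
  q_pul <- (p_pa - p_pv) / params[["r_pul"]]
  q_pvn <- (p_pv - p_la) / params[["r_pv"]]

  dq <- c(
    q_mv = valve_flow_derivative(s$q_mv, p_la - p_lv, params[["mv_ropen"]],
                                 params[["mv_rclosed"]], params[["mv_inert"]]),
    q_av = valve_flow_derivative(s$q_av, p_lv - p_sa, params[["av_ropen"]],
                                 params[["av_rclosed"]], params[["av_inert"]]),
    q_tv = valve_flow_derivative(s$q_tv, p_ra - p_rv, params[["tv_ropen"]],
                                 params[["tv_rclosed"]], params[["tv_inert"]]),
    q_pv = valve_flow_derivative(s$q_pv, p_rv - p_pa, params[["pv_ropen"]],
                                 params[["pv_rclosed"]], params[["pv_inert"]])
  )
  dv <- c(
    v_sa = s$q_av - q_sys,
    v_sv = q_sys - q_sv,
    v_pa = s$q_pv - q_pul,
    v_pv = q_pul - q_pvn,
    v_ra = q_sv - s$q_tv,
    v_la = q_pvn - s$q_mv,
    v_lv = s$q_mv - s$q_av,
    v_rv = s$q_tv - s$q_pv
  )
  c(dv, dq)[names(state)]
}
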