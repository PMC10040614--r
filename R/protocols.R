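#' Activation schedules
#'
#' Builders for the per-patch activation times of the experiment
#' protocols. The baseline schedule activates every patch at the
#' atrioventricular delay, mirroring simultaneous endocardial activation.
#' The bundle-branch-block schedule keeps right-ventricular patches at the
#' AV delay and delays septal and left-ventricular free-wall patches along
#' a myocardial propagation map whose total spread is configurable. The
#' resynchronization schedule paces the tagged LV-epicardial and RV-apical
#' patches at the device AV delay (no interventricular delay) and lets the
#' remaining patches follow a shortened propagation map.
#'
#' @param patches a patch tibble from [default_patches()].
#' @param av_delay sinus atrioventricular delay (ms).
#' @param spread total myocardial activation spread of the delayed wall
#'   (ms).
#' @param paced_delay device atrioventricular delay for paced patches (ms).
#' @return the patch tibble with updated `t_act`.
#' @name schedules
NULL

#' @rdname schedules
#' @export
schedule_baseline <- function(patches, av_delay = 130) {
  patches$t_act <- av_delay
  patches
}

#' @rdname schedules
#' @export
schedule_lbbb <- function(patches, av_delay = 130, spread = 100) {
  ramp <- function(n, from, to) if (n == 1) (from + to) / 2 else seq(from, to, length.out = n)
  t <- patches$t_act
  t[patches$region == "rv_free"] <- av_delay
  i <- patches$region == "septum"
  t[i] <- av_delay + ramp(sum(i), 0.25 * spread, 0.55 * spread)
  i <- patches$region == "lv_free"
  t[i] <- av_delay + ramp(sum(i), 0.5 * spread, spread)
  patches$t_act <- t
  patches
}

#' @rdname schedules
#' @export
schedule_crt <- function(patches, paced_delay = 120, spread = 55) {
  ramp <- function(n, from, to) if (n == 1) (from + to) / 2 else seq(from, to, length.out = n)
  t <- rep(paced_delay, nrow(patches))
  i <- !patches$pace_crt & patches$region == "lv_free"
  t[i] <- paced_delay + ramp(sum(i), 0.3 * spread, spread)
  i <- !patches$pace_crt & patches$region == "septum"
  t[i] <- paced_delay + ramp(sum(i), 0.4 * spread, 0.8 * spread)
  i <- !patches$pace_crt & patches$region == "rv_free"
  t[i] <- paced_delay + ramp(sum(i), 0.2 * spread, 0.6 * spread)
  patches$t_act <- t
  patches
}

mef_variant <- function(config, tension = c("lv", "l0", "10"), sac = TRUE,
                        tref_override = 70) {
  tension <- match.arg(tension)
  config$toggles <- mef_toggles(
    velocity_dependence = tension == "lv",
    length_dependence = tension != "10",
    sac_enabled = sac)
  if (tension != "lv") config$land[["tref"]] <- tref_override
  config
}

#' MEF ablation matrix
#'
#' Runs the six combinations of stretch-activated channels (on/off) and
#' active-tension dependence: full `Ta(lambda, lambdadot)`, velocity
#' dependence removed `Ta(lambda, 0)` (distortion gain set to zero), and
#' additionally length dependence removed `Ta(1, 0)` (`beta0 = beta1 = 0`).
#' The two configurations without velocity dependence use the retuned
#' tension scale (`tref_override`), since removing the shortening-velocity
#' weakening otherwise raises peak tension well above the calibrated
#' baseline.
#'
#' @param config baseline configuration from [heart_config()].
#' @param tref_override tension scale for the velocity-free rows (kPa).
#' @param max_beats,tol forwarded to [run_to_steady_state()].
#' @return a list with `table` (one row per run and ventricle: peak
#'   pressure, stroke volume, max dP/dt, ejection duration) and `runs`
#'   (named list of `cardiomef_run` objects).
#' @export
ablation_matrix <- function(config, tref_override = 70, max_beats = 10,
                            tol = 0.01) {
  grid <- tidyr::expand_grid(sac = c(TRUE, FALSE),
                             tension = c("lv", "l0", "10"))
  runs <- purrr::pmap(grid, function(sac, tension) {
    cfg <- mef_variant(config, tension, sac, tref_override)
    run_to_steady_state(cfg, max_beats = max_beats, tol = tol,
                        min_beats = max_beats)
  })
  label <- function(tension) switch(tension, lv = "Ta(lambda,lambdadot)",
                                    l0 = "Ta(lambda,0)", `10` = "Ta(1,0)")
  names(runs) <- paste0(ifelse(grid$sac, "isac_", "nosac_"), grid$tension)
  tab <- purrr::pmap_df(
    list(runs, grid$sac, grid$tension),
    function(run, sac, tension) {
      m <- beat_metrics(run$sim)$hemo
      mutate(m, sac = sac, tension = label(tension), .before = 1)
    })
  list(table = tab, runs = runs)
}

#' Stretch-trigger sensitivity sweep
#'
#' For each trigger level: recalibrate the stretch-activated conductance,
#' run the heart to steady state (recording failure to converge as a
#' finding, not an error), and summarise the earliest depolarization
#' relative to the stimulus together with the hemodynamics.
#'
#' @param levels trigger levels (stretch fractions in (0, 0.12]).
#' @param config baseline configuration.
#' @param max_beats,tol forwarded to [run_to_steady_state()].
#' @return a list with `table` (per level: calibrated conductance,
#'   convergence, premature-activation lead time, LV features) and `runs`.
#' @export
sac_sweep <- function(levels = c(0.10, 0.09, 0.08, 0.07, 0.06, 0.05),
                      config = heart_config(), max_beats = 10, tol = 0.01) {
  if (any(levels <= 0 | levels > 0.12)) abort("levels must lie in (0, 0.12]")
  runs <- purrr::map(levels, function(lv) {
    cal <- calibrate_sac(lv, cell = config$cell, base = config$sac)
    cfg <- config
    cfg$sac <- cal
    run_to_steady_state(cfg, max_beats = max_beats, tol = tol)
  })
  names(runs) <- sprintf("trigger_%02d", round(100 * levels))
  tab <- purrr::map2_df(runs, levels, function(run, lv) {
    m <- beat_metrics(run$sim)
    h <- m$hemo[m$hemo$side == "lv", ]
    tibble(trigger = lv, g_sac = run$config$sac[["g"]],
           converged = run$converged, premature = run$premature,
           lead_ms = m$activation$lead_ms,
           sv_ml = h$sv_ml, pp_mmhg = h$pp_mmhg, edp_mmhg = h$edp_mmhg)
  })
  list(table = tab, runs = runs)
}

#' Acute left bundle branch block protocol
#'
#' Applies the bundle-branch-block activation schedule to the converged
#' baseline state and simulates exactly two beats; metrics come from the
#' final beat.
#'
#' @param base a `cardiomef_run` from [run_to_steady_state()] (the
#'   baseline), or a configuration (which is first run to steady state).
#' @param spread total LV activation spread of the delay map (ms).
#' @param n_beats number of acute beats.
#' @return a `cardiomef_run`-like list with the acute simulation, metrics
#'   and the schedule used.
#' @export
lbbb_protocol <- function(base, spread = 100, n_beats = 2) {
  if (inherits(base, "cardiomef_config")) base <- run_to_steady_state(base)
  cfg <- base$config
  cfg$patches <- schedule_lbbb(cfg$patches,
                               av_delay = cfg$timing[["av_delay"]],
                               spread = spread)
  sim <- simulate_heart(cfg, n_beats, state = base$state)
  m <- beat_metrics(sim)
  structure(list(sim = sim, state = sim$state, metrics = m, config = cfg,
                 beats = n_beats, baseline = base,
                 schedule = cfg$patches[c("patch", "region", "t_act")]),
            class = "cardiomef_acute")
}

#' Acute cardiac resynchronization protocol
#'
#' Applies biventricular pacing (tagged LV-epicardial and RV-apical
#' patches at the device AV delay, no interventricular delay) on top of a
#' bundle-branch-block result and simulates two acute beats.
#'
#' @param lbbb result of [lbbb_protocol()].
#' @param paced_delay device atrioventricular delay (ms).
#' @param spread propagation spread of the non-paced patches (ms).
#' @param n_beats number of acute beats.
#' @return same shape as [lbbb_protocol()].
#' @export
crt_protocol <- function(lbbb, paced_delay = 120, spread = 55, n_beats = 2) {
  cfg <- lbbb$config
  cfg$patches <- schedule_crt(cfg$patches, paced_delay = paced_delay,
                              spread = spread)
  sim <- simulate_heart(cfg, n_beats, state = lbbb$state)
  m <- beat_metrics(sim)
  structure(list(sim = sim, state = sim$state, metrics = m, config = cfg,
                 beats = n_beats, baseline = lbbb,
                 schedule = cfg$patches[c("patch", "region", "t_act")]),
            class = "cardiomef_acute")
}

#' @export
print.cardiomef_acute <- function(x, ...) {
  h <- x$metrics$hemo
  cat("<cardiomef_acute>", x$beats, "beat(s)\n")
  cat(sprintf("  LV: EDV %.1f mL, SV %.1f mL, PP %.1f mmHg, max dP/dt %.2f\n",
              h$edv_ml[1], h$sv_ml[1], h$pp_mmhg[1], h$max_dpdt[1]))
  invisible(x)
}
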