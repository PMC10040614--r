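# Shared, memoised simulation products so that expensive runs (pacing,
# baseline steady state, protocol sweeps) are computed once per test session.
run_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

paced_epi <- function() {
  memo("paced_epi", suppressWarnings(
    pace_to_steady_state(cell_params("epi"), 600, n_beats_max = 200,
                         tol = 1e-3)$state))
}

base_run <- function() {
  memo("base_run", run_to_steady_state(heart_config()))
}

base_metrics <- function() {
  memo("base_metrics", beat_metrics(base_run()$sim))
}

lbbb_run <- function() {
  memo("lbbb_run", lbbb_protocol(base_run()))
}

crt_run <- function() {
  memo("crt_run", crt_protocol(lbbb_run()))
}

ablation_runs <- function() {
  memo("ablation", ablation_matrix(heart_config()))
}

sac_sweep_runs <- function() {
  memo("sac_sweep", sac_sweep(config = heart_config()))
}

sac_cal_10 <- function() {
  memo("sac_cal_10", calibrate_sac(0.10))
}

# the three MEF tension variants under dispersed activation (criterion-4
# style heterogeneity runs), SAC on, plus the fully MEF-free run
hetero_runs <- function() {
  memo("hetero", {
    cfg0 <- disperse_activation(heart_config(), half_width = 25, seed = 1)
    runs <- lapply(c(lv = "lv", l0 = "l0", `10` = "10"), function(t)
      run_to_steady_state(cardiomef:::mef_variant(cfg0, t, sac = TRUE),
                          max_beats = 10, min_beats = 10))
    runs$none <- run_to_steady_state(
      cardiomef:::mef_variant(cfg0, "10", sac = FALSE),
      max_beats = 10, min_beats = 10)
    runs
  })
}

# stroke-volume response to a 5% total-blood-volume increase, with or
# without length dependence (Frank-Starling probe)
fs_response <- function(length_on) {
  memo(paste0("fs_", length_on), {
    tgl <- mef_toggles(length_dependence = length_on)
    c0 <- heart_config(toggles = tgl)
    c1 <- heart_config(toggles = tgl,
                       init = c(v_sv = unname(c0$init[["v_sv"]]) + 0.05 *
                                  sum(c0$init)))
    s0 <- simulate_heart(c0, 6, record_every = 2)
    s1 <- simulate_heart(c1, 6, record_every = 2)
    beat_metrics(s1, 6)$hemo$sv_ml[1] - beat_metrics(s0, 6)$hemo$sv_ml[1]
  })
}

# max |Vm| difference between the fixed-step Rush-Larsen trace and an
# independent adaptive stiff-solver integration of the same dynamics
ionic_crosscheck_maxerr <- function() {
  memo("ionic_xcheck", {
    p <- cell_params("epi")
    st <- suppressWarnings(pace_to_steady_state(p, 1000, n_beats_max = 40,
                                                tol = 1e-3)$state)
    rl <- simulate_cell(p, state = st, duration = 500, stim_onset = 0,
                        stim_dur = 2, stim_amp = -36, record_every = 1)$trace
    rhs <- function(t, y, parms) {
      names(y) <- names(st)
      iext <- if (t < 2) -36 else 0
      list(as.numeric(cpp_cell_derivs(y, p, iext)))
    }
    seg1 <- deSolve::lsoda(st, seq(0, 2, by = 0.25), rhs, NULL,
                           rtol = 1e-8, atol = 1e-10)
    y2 <- seg1[nrow(seg1), -1]
    seg2 <- deSolve::lsoda(y2, seq(2, 500, by = 1), rhs, NULL,
                           rtol = 1e-8, atol = 1e-10)
    vm_ref <- c(seg1[-nrow(seg1), "V"], seg2[, "V"])
    t_ref <- c(seg1[-nrow(seg1), "time"], seg2[, "time"])
    # align at the interpolated 0-mV upstroke crossing: sub-sample timing
    # offsets between integrators otherwise dominate the pointwise error
    # on the near-vertical upstroke
    t0_ref <- detect_activation_time(data.frame(time_ms = t_ref, vm_mv = vm_ref))
    t0_rl <- detect_activation_time(rl)
    vm_rl <- approx(rl$time_ms - t0_rl + t0_ref, rl$vm_mv, xout = t_ref)$y
    keep <- is.finite(vm_rl) & t_ref >= 5 # past the stimulated upstroke
    max(abs(vm_rl[keep] - vm_ref[keep]))
  })
}
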