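#' Time derivative of the myocyte state
#'
#' Evaluates the full right-hand side of the ionic model, with an external
#' current density (stimulus and/or stretch-activated current) added to the
#' membrane current sum. Every Hodgkin-Huxley gate derivative has the form
#' `(x_inf(Vm) - x) / tau_x(Vm)`.
#'
#' @param state named numeric vector from [cell_state()] (or any valid
#'   19-entry state).
#' @param params parameters from [cell_params()].
#' @param i_external external current density (A/F); positive values are
#'   outward (repolarizing) in the model's current-balance convention.
#' @return named numeric vector of the same shape as `state`.
#' @export
cell_derivatives <- function(state, params = cell_params(), i_external = 0) {
  cpp_cell_derivs(state, params, i_external)
}

#' Advance the myocyte one time step
#'
#' One fixed step of the cell integrator: exponential (Rush-Larsen) updates
#' for the gates - which therefore stay in `[0, 1]` by construction - and a
#' forward update for potential and concentrations.
#'
#' @inheritParams cell_derivatives
#' @param dt step size (ms); must be positive, and at most 0.1 ms is
#'   advisable through the stiff sodium upstroke.
#' @return the advanced state vector.
#' @export
step_cell <- function(state, params = cell_params(), i_external = 0, dt = 0.02) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("dt must be positive")
  cpp_step_cell(state, params, i_external, dt)
}

#' Simulate an isolated myocyte
#'
#' Runs the cell under a rectangular stimulus and an optional stretch
#' waveform driving the stretch-activated current.
#'
#' @param params parameters from [cell_params()].
#' @param state initial state; defaults to the published resting state.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param stim_onset,stim_dur,stim_amp rectangular stimulus timing (ms) and
#'   amplitude (A/F, negative = depolarizing).
#' @param lambda stretch ratio: a single number or a tibble from
#'   [make_stretch()] (column `lambda`, sampled every `dt`).
#' @param sac stretch-activated channel parameters from [sac_params()];
#'   `NULL` disables the channel.
#' @param record_every trace sampling interval (ms).
#' @return a list with `trace` (tibble: `time_ms`, `vm_mv`, `cai_mm`,
#'   `lambda`) and `state` (final state vector).
#' @export
#' @examples
#' sim <- simulate_cell(duration = 400)
#' max(sim$trace$vm_mv) > 0
simulate_cell <- function(params = cell_params(), state = cell_state(),
                          duration = 600, dt = 0.02,
                          stim_onset = 10, stim_dur = 2, stim_amp = -36,
                          lambda = 1, sac = NULL, record_every = 0.5) {
  if (is.null(sac)) sac <- sac_params(g = 0, enabled = FALSE)
  lam <- if (is.data.frame(lambda)) lambda$lambda else lambda
  out <- cpp_run_cell(state, params, sac, lam, duration, dt,
                      stim_onset, stim_dur, stim_amp, record_every)
  list(trace = as_tibble(as.data.frame(out$trace)), state = out$state)
}

#' Pace an isolated cell to periodic steady state
#'
#' Repeatedly stimulates an unstretched cell at a fixed cycle length until
#' the end-diastolic state stops changing between beats (relative
#' state-change tolerance) or the beat budget is exhausted.
#'
#' @param params parameters from [cell_params()].
#' @param cycle_length pacing interval (ms).
#' @param n_beats_max maximum number of beats; `0` returns the initial
#'   conditions unchanged with a warning flag.
#' @param tol maximum relative beat-to-beat state change for convergence.
#' @param dt integration step (ms).
#' @param state initial state.
#' @param stim_dur,stim_amp stimulus applied at the start of each beat.
#' @return a list: `state` (end-diastolic state), `beats`, `converged`
#'   (logical), `delta` (final beat-to-beat change), `criterion` ("tol" or
#'   "max_beats").
#' @export
pace_to_steady_state <- function(params = cell_params(), cycle_length = 600,
                                 n_beats_max = 200, tol = 1e-3, dt = 0.02,
                                 state = cell_state(),
                                 stim_dur = 2, stim_amp = -36) {
  if (cycle_length <= 0) abort("cycle_length must be positive")
  if (n_beats_max == 0) {
    warn("n_beats_max = 0: returning initial conditions unchanged")
    return(list(state = state, beats = 0L, converged = FALSE, delta = NA_real_,
                criterion = "max_beats"))
  }
  out <- cpp_pace_cell(state, params, cycle_length, n_beats_max, tol, dt,
                       stim_dur, stim_amp)
  if (!out$converged)
    warn(sprintf("pacing did not reach tolerance %g in %d beats (delta %.3g)",
                 tol, out$beats, out$delta))
  list(state = out$state, beats = out$beats, converged = out$converged,
       delta = out$delta,
       criterion = if (out$converged) "tol" else "max_beats")
}

# memoised pacing used by calibration and heart initialisation
paced_state_cached <- function(params, cycle_length = 600, n_beats_max = 200,
                               tol = 1e-3) {
  key <- cache_key("pace", params, cycle_length, n_beats_max, tol)
  if (is.null(the_cache[[key]])) {
    res <- suppressWarnings(
      pace_to_steady_state(params, cycle_length, n_beats_max, tol))
    the_cache[[key]] <- res$state
  }
  the_cache[[key]]
}

#' Depolarization time of a membrane-potential trace
#'
#' First upward threshold crossing, linearly interpolated between samples.
#'
#' @param trace a data frame with columns `time_ms` and `vm_mv` (as produced
#'   by [simulate_cell()]), or a numeric Vm vector together with `dt`.
#' @param threshold crossing level (mV).
#' @param dt sample interval (ms) when `trace` is a bare vector.
#' @return crossing time (ms), or `NA` if the threshold is never crossed.
#' @export
#' @examples
#' tr <- tibble::tibble(time_ms = 0:10, vm_mv = seq(-80, 20, length.out = 11))
#' detect_activation_time(tr, 0) # 8
detect_activation_time <- function(trace, threshold = 0, dt = NULL) {
  tv <- as_trace(trace, dt)
  if (nrow(tv) == 0) abort("empty trace")
  v <- tv$vm_mv
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  frac <- (threshold - v[i]) / (v[i + 1] - v[i])
  tv$time_ms[i] + frac * (tv$time_ms[i + 1] - tv$time_ms[i])
}

#' Repolarization time of a membrane-potential trace
#'
#' First downward crossing, after the action-potential peak, of the
#' repolarization criterion: by default 90% of the return from peak toward
#' the pre-stimulus diastolic potential (APD90-style), or an absolute level
#' in mV.
#'
#' @inheritParams detect_activation_time
#' @param level repolarization criterion: a fraction in (0, 1) of the
#'   return toward the diastolic potential, or an absolute level in mV when
#'   `absolute = TRUE`.
#' @param absolute interpret `level` as mV rather than a fraction.
#' @return crossing time (ms), or `NA` when no activation is present.
#' @export
detect_repolarization_time <- function(trace, level = 0.9, absolute = FALSE,
                                       dt = NULL) {
  tv <- as_trace(trace, dt)
  if (nrow(tv) == 0) abort("empty trace")
  v <- tv$vm_mv
  ipk <- which.max(v)
  if (ipk == nrow(tv)) return(NA_real_)
  baseline <- v[1]
  thr <- if (absolute) level else v[ipk] - level * (v[ipk] - baseline)
  if (v[ipk] <= thr) return(NA_real_) # no excursion above the criterion
  vv <- v[ipk:length(v)]
  tt <- tv$time_ms[ipk:length(v)]
  dn <- which(vv[-length(vv)] > thr & vv[-1] <= thr)
  if (!length(dn)) return(NA_real_)
  i <- dn[1]
  frac <- (vv[i] - thr) / (vv[i] - vv[i + 1])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

as_trace <- function(trace, dt = NULL) {
  if (is.data.frame(trace)) {
    if (!all(c("time_ms", "vm_mv") %in% names(trace)))
      abort("trace must have columns time_ms and vm_mv")
    return(trace[c("time_ms", "vm_mv")])
  }
  if (is.numeric(trace)) {
    if (length(trace) == 0) abort("empty trace")
    if (is.null(dt)) abort("dt is required for a bare Vm vector")
    return(tibble(time_ms = (seq_along(trace) - 1) * dt, vm_mv = trace))
  }
  abort("trace must be a data frame or numeric vector")
}
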