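#' Stretch-activated current
#'
#' Sigmoidal stretch-gated current
#' `I = G (Vm - E_SAC) / (1 + K exp(-alpha (lambda - 1)))`: linear in the
#' driving force, saturating toward `G (Vm - E_SAC)` at large stretch.
#' Vectorised over `vm` and `lambda`.
#'
#' @param vm membrane potential (mV).
#' @param lambda fiber stretch ratio (> 0).
#' @param params parameters from [sac_params()].
#' @return current density (A/F); zero when the channel is disabled.
#' @export
#' @examples
#' i_sac(-80, 1.1, sac_params(g = 1)) # about -0.80 A/F
i_sac <- function(vm, lambda, params = sac_params()) {
  if (any(lambda <= 0)) abort("lambda must be positive")
  if (!params[["enabled"]]) return(rep(0, max(length(vm), length(lambda))) * vm * 0)
  params[["g"]] * (vm - params[["e_rev"]]) /
    (1 + params[["k_sig"]] * exp(-params[["alpha"]] * (lambda - 1)))
}

#' Calibrate the stretch-activated conductance to a trigger level
#'
#' Scales the maximal conductance `G` (holding reversal potential and
#' sigmoid shape fixed) so that a sustained stretch step at exactly the
#' trigger level elicits a full action potential (peak Vm > 0 mV) in a
#' paced-to-steady-state cell, while a step one scan increment below the
#' trigger leaves the membrane below -40 mV. The minimal firing conductance
#' is located by bisection on a bracketing interval.
#'
#' @param trigger stretch fraction in (0, 0.2] at which a sustained stretch
#'   must fire (0.10 = 10%).
#' @param cell cell parameters from [cell_params()].
#' @param base starting channel parameters; only `g` is rescaled.
#' @param scan_step stretch increment separating "fires" from "must not
#'   depolarize" (at most 0.01).
#' @param cycle_length pacing and hold interval (ms).
#' @param rel_tol relative bisection tolerance on the scale factor.
#' @return a [sac_params()] vector with calibrated `g`, plus attributes
#'   `scale` (ratio to `base`'s g), `trigger` and `log` (bisection history
#'   tibble).
#' @export
calibrate_sac <- function(trigger = 0.10, cell = cell_params(),
                          base = sac_params(), scan_step = 0.01,
                          cycle_length = 600, rel_tol = 1e-3) {
  if (trigger <= 0 || trigger > 0.2) abort("trigger must lie in (0, 0.2]")
  if (scan_step > 0.01) abort("scan step must be <= 0.01")
  rest <- paced_state_cached(cell, cycle_length)

  peak_vm <- function(g, lam) {
    sac <- base
    sac[["g"]] <- g
    sac[["enabled"]] <- 1
    out <- cpp_run_cell(rest, cell, sac, lam, cycle_length, 0.02,
                        -1, 0, 0, 1)
    max(out$trace[, 2])
  }
  fires <- function(g) peak_vm(g, 1 + trigger) > 0

  log <- list()
  note <- function(g, fired) log[[length(log) + 1]] <<- tibble(g = g, fired = fired)

  # bracket the minimal firing conductance
  g_hi <- if (base[["g"]] > 0) base[["g"]] else 0.01
  tries <- 0
  while (!fires(g_hi)) {
    note(g_hi, FALSE)
    g_hi <- g_hi * 2
    tries <- tries + 1
    if (tries > 40) abort("calibration failure: no conductance in the bracket fires")
  }
  note(g_hi, TRUE)
  g_lo <- g_hi / 2
  while (fires(g_lo)) {
    note(g_lo, TRUE)
    g_hi <- g_lo
    g_lo <- g_lo / 2
    tries <- tries + 1
    if (tries > 80) abort("calibration failure: firing persists at vanishing conductance")
  }
  note(g_lo, FALSE)

  while ((g_hi - g_lo) / g_hi > rel_tol) {
    g_mid <- sqrt(g_lo * g_hi)
    f <- fires(g_mid)
    note(g_mid, f)
    if (f) g_hi <- g_mid else g_lo <- g_mid
  }
  g_star <- g_hi

  # safety condition: one scan step below the trigger must stay subthreshold
  vm_below <- peak_vm(g_star, 1 + trigger - scan_step)
  if (vm_below > -40)
    abort(sprintf(paste0("calibration failure: stretch %.0f%% reaches %.1f mV ",
                         "with the calibrated conductance"),
                  100 * (trigger - scan_step), vm_below))

  out <- base
  out[["g"]] <- g_star
  out[["enabled"]] <- 1
  structure(out,
            class = class(base),
            scale = g_star / base[["g"]],
            trigger = trigger,
            log = dplyr::bind_rows(log))
}
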