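#' Stretch waveform generator
#'
#' Builds sampled stretch protocols for driving the single-cell models:
#' the stretch-rate column is the exact analytic derivative of the shape,
#' not a finite difference. Step protocols have zero reported rate away
#' from the (instantaneous) jump.
#'
#' @param kind one of `"hold"`, `"step"`, `"ramp"`, `"sinusoid"`,
#'   `"quick_release"`.
#' @param baseline resting stretch ratio.
#' @param amplitude excursion from baseline (sign allowed).
#' @param onset start of the excursion (ms).
#' @param duration total protocol duration (ms).
#' @param rate ramp slope (stretch/ms) for `"ramp"`.
#' @param period sinusoid period (ms).
#' @param dt sample interval (ms).
#' @return tibble with `time_ms`, `lambda`, `lambda_dot`.
#' @export
#' @examples
#' s <- make_stretch("step", amplitude = 0.10, onset = 100, duration = 600)
#' range(s$lambda)
make_stretch <- function(kind = c("hold", "step", "ramp", "sinusoid",
                                  "quick_release"),
                         baseline = 1, amplitude = 0.1, onset = 0,
                         duration = 600, rate = 0.001, period = 200,
                         dt = 0.02) {
  kind <- match.arg(kind)
  if (onset < 0 || duration <= 0) abort("onset must be >= 0 and duration > 0")
  t <- seq(0, duration, by = dt)
  lam <- rep(baseline, length(t))
  lam_dot <- rep(0, length(t))
  after <- t >= onset
  if (kind == "step") {
    lam[after] <- baseline + amplitude
  } else if (kind == "quick_release") {
    lam[!after] <- baseline + amplitude
    lam[after] <- baseline
  } else if (kind == "ramp") {
    dur_ramp <- abs(amplitude / rate)
    tt <- pmax(0, pmin(t - onset, dur_ramp))
    lam <- baseline + sign(amplitude) * rate * tt
    lam_dot <- ifelse(t >= onset & t < onset + dur_ramp, sign(amplitude) * rate, 0)
  } else if (kind == "sinusoid") {
    w <- 2 * pi / period
    tt <- t - onset
    lam[after] <- baseline + amplitude * sin(w * tt[after])
    lam_dot[after] <- amplitude * w * cos(w * tt[after])
  }
  if (any(lam <= 0.7 | lam >= 1.3))
    abort("stretch protocol leaves the admissible range (0.7, 1.3)")
  tibble(time_ms = t, lambda = lam, lambda_dot = lam_dot)
}

#' Synthetic calcium transient
#'
#' Smooth single-peak transient
#' `Cai(t) = dia + amp (t/tau_p) exp(1 - t/tau_p)` per cycle (peak value
#' `dia + amp` exactly at `t = tau_p`), repeated periodically. A surrogate
#' for the ionic model's calcium when exercising the tension model alone.
#'
#' @param diastolic resting calcium (mM).
#' @param amplitude peak minus diastolic (mM).
#' @param time_to_peak `tau_p` (ms).
#' @param cycle_length period (ms).
#' @param n_cycles number of repeated cycles.
#' @param dt sample interval (ms).
#' @return tibble with `time_ms`, `cai_mm`.
#' @export
make_calcium <- function(diastolic = 1.3e-4, amplitude = 1.1e-3,
                         time_to_peak = 30, cycle_length = 600,
                         n_cycles = 1, dt = 0.1) {
  if (any(c(diastolic, amplitude, time_to_peak, cycle_length) <= 0))
    abort("all calcium-transient parameters must be positive")
  t <- seq(0, n_cycles * cycle_length, by = dt)
  tc <- t %% cycle_length
  cai <- diastolic + amplitude * (tc / time_to_peak) * exp(1 - tc / time_to_peak)
  tibble(time_ms = t, cai_mm = cai)
}

#' Ready-made small configurations
#'
#' A registry of fully specified, fast-running setups used across the test
#' suite and examples:
#' \describe{
#'   \item{single-cell}{cell + channel + tension parameter set for isolated
#'     myocyte work.}
#'   \item{two-patch-toy}{a two-patch ventricle with 10% reference-area
#'     asymmetry for equilibrium-solver oracles.}
#'   \item{mini-heart}{a reduced closed-loop heart (4 patches per
#'     ventricle, 2 beats) for smoke tests.}
#' }
#'
#' @param name registry key.
#' @return a list; contents depend on the fixture (see Details).
#' @export
make_fixture <- function(name = c("single-cell", "two-patch-toy", "mini-heart")) {
  name <- match.arg(name)
  switch(name,
    "single-cell" = list(
      cell = cell_params("epi"),
      sac = sac_params(),
      land = land_params(),
      calcium = make_calcium(),
      seed = 1L
    ),
    "two-patch-toy" = list(
      vent = ventricle(aref = c(10, 11), vwall = c(40, 44)),
      passive = passive_params(),
      seed = 1L
    ),
    "mini-heart" = {
      cfg <- heart_config(n_patches_lv = 4, n_septal = 1, n_patches_rv = 4)
      list(config = cfg, n_beats = 2L, seed = 1L)
    }
  )
}

#' Disperse patch activation times
#'
#' Adds seed-deterministic uniform jitter (half-width `half_width` ms) to
#' every patch activation time of a configuration. Used to emulate the
#' activation-time heterogeneity that a propagating wavefront produces over
#' the walls, which the 0D surrogate otherwise lacks.
#'
#' @param config a [heart_config()].
#' @param half_width jitter half-width (ms).
#' @param seed RNG seed recorded in the result.
#' @return the configuration with jittered `t_act` and attribute `seed`.
#' @export
disperse_activation <- function(config, half_width = 25, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jit <- runif(nrow(config$patches), -half_width, half_width)
  config$patches$t_act <- config$patches$t_act + jit
  attr(config, "jitter_seed") <- seed
  config
}
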