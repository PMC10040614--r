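test_that("gate derivatives vanish at their voltage-dependent steady state", {
  # each gate obeys dx/dt = (x_inf - x)/tau, linear in x: recover x_inf
  # from two evaluations, then the derivative at x_inf must vanish
  p <- cell_params("epi")
  for (g in c("m", "h", "j", "d", "f", "xs", "r", "s")) {
    s0 <- cell_state(); s0[[g]] <- 0
    s1 <- cell_state(); s1[[g]] <- 1
    d0 <- cell_derivatives(s0, p)[[g]]
    d1 <- cell_derivatives(s1, p)[[g]]
    tau <- 1 / (d0 - d1)
    xinf <- d0 * tau
    se <- cell_state(); se[[g]] <- xinf
    expect_lt(abs(cell_derivatives(se, p)[[g]]), 1e-10)
  }
})

test_that("external current enters the balance linearly with unit weight", {
  s <- cell_state()
  p <- cell_params()
  d0 <- cell_derivatives(s, p, i_external = 0)
  d1 <- cell_derivatives(s, p, i_external = 2.5)
  expect_equal(d1[["V"]] - d0[["V"]], -2.5, tolerance = 1e-12)
  # other immediate derivatives except K+ bookkeeping are unchanged
  expect_equal(d1[["Cai"]], d0[["Cai"]], tolerance = 1e-15)
  expect_equal(d1[["m"]], d0[["m"]], tolerance = 1e-15)
})

test_that("non-finite state components are rejected", {
  s <- cell_state()
  s[["Cai"]] <- NaN
  expect_error(cell_derivatives(s), "non-finite")
  expect_error(step_cell(cell_state(), dt = -1), "positive")
})

test_that("the paced diastolic state is a near-fixed point of the dynamics", {
  paced <- paced_epi()
  d <- cell_derivatives(paced, cell_params("epi"), 0)
  expect_lt(abs(d[["V"]]), 0.01)
  # diastolic potential in the published resting range
  expect_gt(paced[["V"]], -90)
  expect_lt(paced[["V"]], -80)
})

test_that("integration is continuous in dt and step-halving consistent", {
  paced <- paced_epi()
  tiny <- step_cell(paced, dt = 1e-7)
  expect_equal(unclass(tiny), unclass(paced), tolerance = 1e-6)
  full <- step_cell(paced, dt = 0.02)
  halves <- step_cell(step_cell(paced, dt = 0.01), dt = 0.01)
  expect_lt(abs(full[["V"]] - halves[["V"]]), 0.01)
})

test_that("a suprathreshold stimulus elicits a fast upstroke", {
  sim <- simulate_cell(state = paced_epi(), duration = 20, stim_onset = 2,
                       stim_dur = 2, stim_amp = -36, record_every = 0.1)
  tr <- sim$trace
  expect_gt(max(tr$vm_mv), 10)
  expect_lt(tr$time_ms[which.max(tr$vm_mv)], 7) # peak within 5 ms of onset
})

test_that("gates stay in [0,1] and concentrations positive over a long run", {
  p <- cell_params("epi")
  y <- paced_epi()
  lo <- rep(Inf, 19); hi <- rep(-Inf, 19)
  for (i in 1:10000) {
    iext <- if (i %% 3000 < 100) -36 else 0 # repeated stimuli
    y <- cpp_step_cell(y, p, iext, 0.02)
    lo <- pmin(lo, y); hi <- pmax(hi, y)
  }
  expect_true(all(lo[7:18] >= 0) && all(hi[7:18] <= 1))
  expect_true(all(lo[2:6] > 0))
})

test_that("an early second stimulus does not regenerate an action potential", {
  paced <- paced_epi()
  seg1 <- simulate_cell(state = paced, duration = 60, stim_onset = 10,
                        record_every = 0.2)
  with2 <- simulate_cell(state = seg1$state, duration = 150, stim_onset = 0,
                         record_every = 0.2)
  ctrl <- simulate_cell(state = seg1$state, duration = 150, stim_onset = -10,
                        stim_dur = 0, stim_amp = 0, record_every = 0.2)
  # no regenerative sodium upstroke follows the early stimulus: the
  # maximal post-stimulus depolarization rate stays far below an action
  # potential's (~300 mV/ms), while the same stimulus from rest produces one
  after <- with2$trace$time_ms > 3
  dvdt2 <- max(diff(with2$trace$vm_mv[after]) / 0.2)
  expect_lt(dvdt2, 30)
  fresh <- simulate_cell(state = paced, duration = 20, stim_onset = 2,
                         record_every = 0.2)
  expect_gt(max(diff(fresh$trace$vm_mv) / 0.2), 100)
})

test_that("action potentials shorten at faster pacing", {
  apd <- function(cl) {
    st <- suppressWarnings(pace_to_steady_state(cycle_length = cl,
                                                n_beats_max = 40,
                                                tol = 1e-3)$state)
    tr <- simulate_cell(state = st, duration = cl, stim_onset = 0,
                        record_every = 0.5)$trace
    detect_repolarization_time(tr, 0.9)
  }
  expect_lt(apd(600), apd(1000))
})

test_that("pacing handles degenerate and converged inputs", {
  expect_warning(res <- pace_to_steady_state(n_beats_max = 0), "unchanged")
  expect_identical(res$beats, 0L)
  expect_equal(res$state, cell_state())
  again <- pace_to_steady_state(state = paced_epi(), n_beats_max = 1,
                                tol = 1e-3)
  expect_true(again$converged)
  expect_lt(again$delta, 1e-3)
})

test_that("activation detection interpolates the threshold crossing", {
  tr <- tibble::tibble(time_ms = 0:10, vm_mv = seq(-80, 20, length.out = 11))
  expect_equal(detect_activation_time(tr, 0), 8)
  flat <- tibble::tibble(time_ms = 0:10, vm_mv = rep(-80, 11))
  expect_true(is.na(detect_activation_time(flat, 0)))
  expect_error(detect_activation_time(tr[0, ], 0), "empty")
  # interpolated crossing agrees with a brute-force sample scan within dt
  sim <- simulate_cell(state = paced_epi(), duration = 30, stim_onset = 5,
                       record_every = 0.1)
  t_interp <- detect_activation_time(sim$trace, 0)
  scan <- sim$trace$time_ms[which(sim$trace$vm_mv >= 0)[1]]
  expect_lt(abs(t_interp - scan), 0.1 + 1e-9)
})

test_that("repolarization detection matches the triangle-wave hand value", {
  t <- seq(0, 305, by = 0.5)
  vm <- ifelse(t <= 5, -80 + 20 * t, 20 - (t - 5) / 3)
  tr <- tibble::tibble(time_ms = t, vm_mv = vm)
  expect_equal(detect_repolarization_time(tr, 0.9), 275, tolerance = 1e-6)
  flat <- tibble::tibble(time_ms = t, vm_mv = rep(-80, length(t)))
  expect_true(is.na(detect_repolarization_time(flat)))
  shifted <- tr
  shifted$time_ms <- shifted$time_ms + 123
  expect_equal(detect_repolarization_time(shifted, 0.9) - 123, 275,
               tolerance = 1e-6)
})

test_that("the fixed-step trace matches an independent stiff-solver route", {
  expect_lt(ionic_crosscheck_maxerr(), 1)
})
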