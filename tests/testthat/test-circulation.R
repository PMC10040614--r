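test_that("open-valve steady flow satisfies the orifice law", {
  # dq/dt = 0  =>  q = sqrt(dP / R_open) for forward flow (no laminar term)
  q_ss <- sqrt(5 / 25)
  expect_equal(valve_flow_derivative(q_ss, 5, 25, 1e10, 5), 0, tolerance = 1e-4)
  expect_equal(valve_flow_derivative(0, 0, 25, 1e10, 5), 0, tolerance = 1e-6)
})

test_that("a closed valve only leaks, never sustains large reverse flow", {
  rhs <- function(t, y, parms)
    list(valve_flow_derivative(y, -20, 25, 1e10, 5))
  out <- deSolve::lsoda(c(q = 0.2), seq(0, 30, by = 0.1), rhs, NULL,
                        rtol = 1e-8, atol = 1e-12)
  leak <- -sqrt(20 / 1e10)
  expect_lt(abs(out[nrow(out), "q"] - leak), 1e-4)
  expect_gt(min(out[, "q"]), -5e-4)
})

test_that("atrial elastance produces the configured pressure sweep", {
  p <- circ_params(e_min_ra = 0.05, e_max_ra = 0.3, v0_ra = 10,
                   t_atr_dur = 150)
  v <- 50 # V - V_unstressed = 40
  expect_equal(atrial_pressure(v, 300, p, "ra"), 0.05 * 40) # diastole
  expect_equal(atrial_pressure(v, 75, p, "ra"), 0.3 * 40)   # twitch peak
  # periodic with the cycle length
  expect_equal(atrial_pressure(v, 40, p, "ra"), atrial_pressure(v, 640, p, "ra"))
  # left atrium delayed by the inter-atrial delay
  expect_equal(atrial_pressure(v, 75 + p[["la_delay"]], p, "la",
                               cycle_length = 600),
               (p[["e_min_la"]] + (p[["e_max_la"]] - p[["e_min_la"]])) *
                 (v - p[["v0_la"]]))
  expect_error(atrial_pressure(-1, 0, p), "positive")
})

test_that("circulation volume derivatives sum to zero exactly", {
  p <- circ_params()
  state <- c(v_sa = 120, v_sv = 150, v_pa = 80, v_pv = 130, v_ra = 20,
             v_la = 60, v_lv = 55, v_rv = 60,
             q_mv = 0.1, q_av = 0, q_tv = 0.05, q_pv = 0)
  d <- circulation_derivatives(state, t = 300, p_lv = 40, p_rv = 12, p = p)
  expect_equal(sum(d[1:8][grepl("^v_", names(d[1:8]))]), 0, tolerance = 1e-15)
  vols <- d[c("v_sa", "v_sv", "v_pa", "v_pv", "v_ra", "v_la", "v_lv", "v_rv")]
  expect_equal(sum(vols), 0, tolerance = 1e-15)
})

test_that("a pressure-equilibrated loop with no flows is stationary", {
  p <- circ_params()
  P <- 6 # common pressure, evaluated in atrial diastole (t = 400)
  state <- c(v_sa = p[["v0_sa"]] + P * p[["c_sa"]],
             v_sv = p[["v0_sv"]] + P * p[["c_sv"]],
             v_pa = p[["v0_pa"]] + P * p[["c_pa"]],
             v_pv = p[["v0_pv"]] + P * p[["c_pv"]],
             v_ra = p[["v0_ra"]] + P / p[["e_min_ra"]],
             v_la = p[["v0_la"]] + P / p[["e_min_la"]],
             v_lv = 50, v_rv = 50,
             q_mv = 0, q_av = 0, q_tv = 0, q_pv = 0)
  d <- circulation_derivatives(state, t = 400, p_lv = P, p_rv = P, p = p)
  expect_equal(max(abs(d[1:8])), 0, tolerance = 1e-10)
})

test_that("total blood volume is conserved through a coupled beat", {
  sim <- memo("mini2", simulate_heart(make_fixture("mini-heart")$config, 2))
  tot <- sim$hemo$total_volume
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})

test_that("no valve carries sustained retrograde mean flow", {
  run <- base_run()
  h <- dplyr::filter(run$sim$hemo, beat == max(beat))
  for (q in c("q_mv", "q_av", "q_tv", "q_pv"))
    expect_gt(mean(h[[q]]), 0)
})

test_that("the left-ventricular loop is traversed counterclockwise", {
  run <- base_run()
  h <- dplyr::filter(run$sim$hemo, beat == max(beat))
  x <- h$v_lv; y <- h$p_lv
  n <- length(x)
  shoelace <- 0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(shoelace, 0)
})

test_that("identical configurations give bitwise identical trajectories", {
  cfg <- make_fixture("mini-heart")$config
  s1 <- simulate_heart(cfg, 1)
  s2 <- simulate_heart(cfg, 1)
  expect_identical(s1$hemo, s2$hemo)
  expect_identical(s1$patch, s2$patch)
})

test_that("preload rise raises stroke volume more with length dependence on", {
  d_on <- fs_response(TRUE)
  d_off <- fs_response(FALSE)
  expect_gt(d_on, 0)
  expect_gt(d_on, d_off)
})

test_that("halving the mechanics step changes stroke volume by < 0.5%", {
  cfg1 <- heart_config()
  cfg2 <- heart_config(dt_mech = 0.1, ep_substeps = 5, tension_every = 5,
                       circ_substeps = 1)
  sv1 <- beat_metrics(simulate_heart(cfg1, 3, record_every = 1), 3)$hemo$sv_ml[1]
  sv2 <- beat_metrics(simulate_heart(cfg2, 3, record_every = 1), 3)$hemo$sv_ml[1]
  expect_lt(abs(sv1 - sv2) / sv1, 0.005)
})
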