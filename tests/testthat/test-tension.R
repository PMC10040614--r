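test_that("length factor evaluates its clamps and floor exactly", {
  expect_equal(length_factor(1, 2), 1)
  expect_equal(length_factor(1, 17), 1) # resting length for any beta0
  expect_equal(length_factor(1.1, 2), 1.2)
  expect_equal(length_factor(1.3, 2), length_factor(1.2, 2)) # 1.2 clamp
  expect_equal(length_factor(0.5, 2), 0)                     # floor
  # continuity across both clamp points
  eps <- 1e-9
  expect_equal(length_factor(0.87 - eps, 2.3), length_factor(0.87 + eps, 2.3),
               tolerance = 1e-7)
  expect_equal(length_factor(1.2 - eps, 2.3), length_factor(1.2 + eps, 2.3),
               tolerance = 1e-7)
})

test_that("calcium sensitivity shifts linearly with stretch up to the clamp", {
  expect_equal(ca50(1, 1.5, 0.8), 0.8)
  expect_equal(ca50(1.25, 1.5, 0.8), 1.1) # clamped at 1.2
  expect_equal(ca50(c(0.9, 1.1, 1.3), 0, 0.8), rep(0.8, 3))
})

test_that("distortion dynamics follow the printed linear ODEs", {
  lp <- land_params()
  st <- land_state(lp)
  st[["zeta_s"]] <- 0.4
  d <- land_derivatives(st, 1, 0, 1e-4, lp)
  expect_equal(d[["zeta_s"]], -lp[["cs"]] * 0.4, tolerance = 1e-12)
  # constant stretch rate: steady distortion Aeff * v / cs
  v <- 5e-4
  n <- 20000
  out <- cpp_run_land(land_state(lp), lp, rep(1e-4, n), rep(1.05, n),
                      rep(v, n), 0.1, TRUE, TRUE)
  expect_equal(out$state[["zeta_s"]], lp[["aeff"]] * v / lp[["cs"]],
               tolerance = 1e-3)
  # velocity toggle removes the drive
  d0 <- land_derivatives(st, 1, v, 1e-4, lp,
                         mef_toggles(velocity_dependence = FALSE))
  expect_equal(d0[["zeta_s"]], -lp[["cs"]] * 0.4, tolerance = 1e-12)
})

test_that("troponin occupancy stays driven into [0, 1]", {
  lp <- land_params()
  st <- land_state(lp)
  st[["CaTRPN"]] <- 1
  expect_lt(land_derivatives(st, 1, 0, 1e-4, lp)[["CaTRPN"]], 0)
  st[["CaTRPN"]] <- 0
  expect_gt(land_derivatives(st, 1, 0, 1e-3, lp)[["CaTRPN"]], 0)
  expect_error(land_derivatives(st, 1, 0, -1, lp), "positive")
})

test_that("tension output reduces to the printed formula", {
  lp <- land_params()
  st <- land_state(lp)
  st[c("S", "W", "zeta_s", "zeta_w")] <- c(0, 0, 0, 0)
  expect_equal(active_tension(st, 1.1, lp), 0)
  st[["S"]] <- 0.1
  expect_equal(active_tension(st, 1.1, lp),
               length_factor(1.1, lp[["beta0"]]) * lp[["tref"]] / lp[["rs"]] * 0.1,
               tolerance = 1e-12)
  # with length dependence off, h is identically one
  expect_equal(active_tension(st, 1.1, lp, mef_toggles(length_dependence = FALSE)),
               lp[["tref"]] / lp[["rs"]] * 0.1, tolerance = 1e-12)
  # tension is floored at zero
  st[["zeta_s"]] <- -2
  expect_equal(active_tension(st, 1.1, lp), 0)
})

test_that("isometric twitches show activation, determinism and Frank-Starling", {
  ca <- make_calcium()
  tw0 <- isometric_twitch(calcium = make_calcium(amplitude = 1e-9))
  expect_lt(tw0$peak, 0.01 * land_params()[["tref"]])
  tw1 <- isometric_twitch(calcium = ca, lambda = 1)
  tw1b <- isometric_twitch(calcium = ca, lambda = 1)
  expect_identical(tw1$trace, tw1b$trace)
  tw2 <- isometric_twitch(calcium = ca, lambda = 1.1)
  expect_gt(tw2$peak, tw1$peak) # cellular Frank-Starling with beta0, beta1 on
})

test_that("removing velocity dependence raises peak tension while shortening", {
  lp <- land_params()
  st <- land_state(lp)
  ca <- make_calcium(dt = 0.1)
  shorten <- make_stretch("ramp", baseline = 1.05, amplitude = -0.1,
                          onset = 60, rate = 5e-4, duration = 600, dt = 0.1)
  on <- cpp_run_land(st, lp, ca$cai_mm, shorten$lambda, shorten$lambda_dot,
                     0.1, TRUE, TRUE)
  off <- cpp_run_land(st, lp, ca$cai_mm, shorten$lambda, shorten$lambda_dot,
                      0.1, FALSE, TRUE)
  expect_gt(max(off$tension), max(on$tension))
})

test_that("without length and velocity dependence tension ignores stretch history", {
  lp <- land_params()
  st <- land_state(lp)
  ca <- make_calcium(dt = 0.1)
  s1 <- make_stretch("sinusoid", amplitude = 0.08, period = 300,
                     duration = 600, dt = 0.1)
  s2 <- make_stretch("hold", baseline = 1.1, duration = 600, dt = 0.1)
  r1 <- cpp_run_land(st, lp, ca$cai_mm, s1$lambda, s1$lambda_dot, 0.1,
                     FALSE, FALSE)
  r2 <- cpp_run_land(st, lp, ca$cai_mm, s2$lambda, s2$lambda_dot, 0.1,
                     FALSE, FALSE)
  expect_equal(r1$tension, r2$tension, tolerance = 1e-12)
})

test_that("state fractions remain bounded with S + W + B <= 1", {
  lp <- land_params()
  st <- land_state(lp)
  ca <- make_calcium(n_cycles = 2, dt = 0.1)
  s <- make_stretch("sinusoid", amplitude = 0.08, period = 250,
                    duration = 1200, dt = 0.1)
  y <- st
  ok <- TRUE
  for (k in seq(1, nrow(ca), by = 50)) {
    out <- cpp_run_land(y, lp, ca$cai_mm[k:min(k + 49, nrow(ca))],
                        s$lambda[k:min(k + 49, nrow(s))],
                        s$lambda_dot[k:min(k + 49, nrow(s))], 0.1, TRUE, TRUE)
    y <- out$state
    f <- y[c("S", "W", "CaTRPN", "B")]
    if (any(f < 0) || any(f > 1) || sum(y[c("S", "W", "B")]) > 1 + 1e-9)
      ok <- FALSE
  }
  expect_true(ok)
})
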