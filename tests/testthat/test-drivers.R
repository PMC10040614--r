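test_that("stretch protocols carry exact analytic rates", {
  h <- make_stretch("hold", baseline = 1, duration = 10, dt = 0.1)
  expect_true(all(h$lambda == 1) && all(h$lambda_dot == 0))

  s <- make_stretch("step", amplitude = 0.1, onset = 100, duration = 200,
                    dt = 0.5)
  expect_equal(s$lambda[s$time_ms == 99], 1)
  expect_equal(s$lambda[s$time_ms == 101], 1.1)

  w <- 2 * pi / 200
  sn <- make_stretch("sinusoid", amplitude = 0.05, period = 200,
                     duration = 400, dt = 0.1)
  expect_equal(max(abs(sn$lambda_dot)), 0.05 * w, tolerance = 1e-4)
  k <- 1000
  expect_equal(sn$lambda_dot[k], 0.05 * w * cos(w * sn$time_ms[k]),
               tolerance = 1e-12)

  r <- make_stretch("ramp", amplitude = 0.1, onset = 50, rate = 0.002,
                    duration = 200, dt = 0.1)
  expect_equal(max(r$lambda), 1.1, tolerance = 1e-9)
  expect_true(all(r$lambda_dot[r$time_ms > 50 & r$time_ms < 99] == 0.002))

  expect_error(make_stretch("step", amplitude = 0.4), "admissible")
})

test_that("the calcium transient peaks exactly at its time-to-peak", {
  ca <- make_calcium(diastolic = 1e-4, amplitude = 1e-3, time_to_peak = 30,
                     dt = 0.1)
  expect_equal(max(ca$cai_mm), 1e-4 + 1e-3, tolerance = 1e-9)
  expect_equal(ca$time_ms[which.max(ca$cai_mm)], 30)
  flat <- make_calcium(amplitude = 1e-12)
  expect_lt(diff(range(flat$cai_mm)), 1e-11)
  # sampling refinement leaves the peak unchanged
  fine <- make_calcium(diastolic = 1e-4, amplitude = 1e-3,
                       time_to_peak = 30, dt = 0.05)
  expect_lt(abs(max(fine$cai_mm) - max(ca$cai_mm)) / max(ca$cai_mm), 1e-6)
  expect_error(make_calcium(amplitude = -1), "positive")
})

test_that("the fixture registry is deterministic and complete", {
  expect_error(make_fixture("nope"))
  two <- make_fixture("two-patch-toy")
  expect_s3_class(two$vent, "cardiomef_ventricle")
  expect_equal(two$vent$aref[2] / two$vent$aref[1], 1.1)
  a <- make_fixture("mini-heart")
  b <- make_fixture("mini-heart")
  expect_identical(a, b)
})

test_that("the mini-heart fixture completes two beats quickly", {
  fix <- make_fixture("mini-heart")
  t0 <- Sys.time()
  sim <- simulate_heart(fix$config, fix$n_beats)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
  expect_equal(max(sim$hemo$beat), 2)
})

test_that("activation dispersion is seed-deterministic and bounded", {
  c1 <- disperse_activation(heart_config(), half_width = 25, seed = 7)
  c2 <- disperse_activation(heart_config(), half_width = 25, seed = 7)
  c3 <- disperse_activation(heart_config(), half_width = 25, seed = 8)
  expect_identical(c1$patches$t_act, c2$patches$t_act)
  expect_false(identical(c1$patches$t_act, c3$patches$t_act))
  expect_true(all(abs(c1$patches$t_act - 130) <= 25))
})

test_that("configurations round-trip through JSON exactly", {
  cfg <- make_fixture("mini-heart")$config
  path <- withr::local_tempfile(fileext = ".json")
  write_heart_config(cfg, path)
  back <- read_heart_config(path)
  expect_equal(unclass(back$land), unclass(cfg$land), tolerance = 1e-15)
  expect_equal(unclass(back$circ), unclass(cfg$circ), tolerance = 1e-15)
  expect_equal(back$patches$t_act, as.numeric(cfg$patches$t_act))
  s1 <- simulate_heart(cfg, 1)
  s2 <- simulate_heart(back, 1)
  expect_equal(s1$hemo$v_lv, s2$hemo$v_lv, tolerance = 1e-9)
})
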