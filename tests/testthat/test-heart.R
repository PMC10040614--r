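test_that("identical, simultaneously activated patches stay identical", {
  cfg <- heart_config()
  sim <- memo("base_2beats", simulate_heart(cfg, 2))
  p <- sim$patch
  lv <- dplyr::filter(p, ventricle == "lv")
  spread <- lv %>%
    dplyr::group_by(time_ms) %>%
    dplyr::summarise(d = max(lambda) - min(lambda),
                     dta = max(tension_kpa) - min(tension_kpa))
  expect_lt(max(spread$d), 1e-12)
  expect_lt(max(spread$dta), 1e-9)
})

test_that("stretch rates vanish when the cavity volume is constant", {
  sim <- memo("base_2beats", simulate_heart(heart_config(), 2))
  h <- dplyr::filter(sim$hemo, beat == 2)
  p <- dplyr::filter(sim$patch, beat == 2)
  dv <- abs(diff(h$v_lv))
  # samples inside the isovolumetric phases (volume change per ms at the
  # closed-valve leak level): the backward-difference rates must be tiny
  iso <- which(dv[-1] < 5e-4 & dv[-length(dv)] < 5e-4) + 1
  iso <- iso[iso > 5]
  expect_gt(length(iso), 10)
  t_iso <- h$time_ms[iso[5]]
  rates <- dplyr::filter(p, time_ms == t_iso, ventricle == "lv")$lambda_dot
  expect_lt(max(abs(rates)), 1e-4)
})

test_that("the pressure-flow fixed point converges within its budget", {
  sim <- memo("base_2beats", simulate_heart(heart_config(), 2))
  expect_true(sim$fp_converged)
  expect_lte(sim$max_fp_iterations, 50)
})

test_that("state continuation reproduces an uninterrupted simulation", {
  cfg <- make_fixture("mini-heart")$config
  whole <- simulate_heart(cfg, 2)
  part1 <- simulate_heart(cfg, 1)
  part2 <- simulate_heart(cfg, 1, state = part1$state)
  expect_equal(part2$state$circ, whole$state$circ, tolerance = 1e-12)
  expect_equal(part2$state$cells, whole$state$cells, tolerance = 1e-12)
})

test_that("an unstimulated patch fires by stretch when SAC is sensitized", {
  # one LV patch never stimulated; with a low-trigger channel the stretch
  # imposed by its contracting neighbours depolarizes it
  cal <- memo("cal05", calibrate_sac(0.05))
  cfg <- heart_config(sac = cal)
  cfg$patches$t_act[1] <- 1e9
  sim <- simulate_heart(cfg, 2)
  p1 <- dplyr::filter(sim$patch, patch == 1, beat == 2)
  expect_gt(max(p1$vm_mv), 0)
  # without the channel the same silent patch stays subthreshold
  cfg2 <- heart_config(toggles = mef_toggles(sac_enabled = FALSE))
  cfg2$patches$t_act[1] <- 1e9
  sim2 <- simulate_heart(cfg2, 2)
  expect_lt(max(dplyr::filter(sim2$patch, patch == 1, beat == 2)$vm_mv), -40)
})
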