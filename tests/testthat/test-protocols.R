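test_that("a converged state re-converges in one beat", {
  run <- base_run()
  again <- run_to_steady_state(heart_config(), state = run$state)
  expect_true(again$converged)
  expect_lte(again$beats, 2)
})

test_that("the baseline reaches steady state within ten beats", {
  run <- base_run()
  expect_true(run$converged)
  expect_lte(run$beats, 10)
  expect_false(run$premature)
})

test_that("experiments are pure functions of their configuration", {
  t1 <- glance(run_to_steady_state(heart_config(), max_beats = 2))
  t2 <- glance(run_to_steady_state(heart_config(), max_beats = 2))
  expect_identical(t1, t2)
})

test_that("ablation applies the retuned tension scale and emits six rows", {
  ab <- ablation_runs()
  expect_equal(nrow(ab$table), 12) # 6 runs x 2 ventricles
  expect_equal(ab$runs$isac_l0$config$land[["tref"]], 70)
  expect_equal(ab$runs$isac_10$config$land[["tref"]], 70)
  expect_gt(ab$runs$isac_lv$config$land[["tref"]], 70)
  expect_equal(unname(ab$runs$isac_10$config$toggles),
               unname(mef_toggles(FALSE, FALSE, TRUE)))
})

test_that("ablation reproduces the Table-1 orderings for the LV", {
  t <- dplyr::filter(ablation_runs()$table, side == "lv", sac)
  lv <- t[t$tension == "Ta(lambda,lambdadot)", ]
  l0 <- t[t$tension == "Ta(lambda,0)", ]
  t10 <- t[t$tension == "Ta(1,0)", ]
  # ejection duration: full MEF > Ta(1,0) > Ta(lambda,0)
  expect_gt(lv$ejection_ms, t10$ejection_ms)
  expect_gt(t10$ejection_ms, l0$ejection_ms)
  # max dP/dt: full MEF > Ta(lambda,0) > Ta(1,0)
  expect_gt(lv$max_dpdt, l0$max_dpdt)
  expect_gt(l0$max_dpdt, t10$max_dpdt)
})

test_that("trigger sweep is safe at high levels and monotone below", {
  sw <- sac_sweep_runs()$table
  high <- sw[sw$trigger >= 0.08, ]
  expect_true(all(!high$premature))
  expect_true(all(high$lead_ms == 0))
  # decreasing level advances (or leaves unchanged) the earliest activation
  ord <- order(-sw$trigger)
  expect_true(all(diff(sw$lead_ms[ord]) >= -1e-9))
})

test_that("bundle-branch block degrades the left ventricle acutely", {
  b <- base_metrics()$hemo
  lb <- lbbb_run()
  l <- lb$metrics$hemo
  expect_lt(l$sv_ml[1], b$sv_ml[1])
  expect_lt(l$pp_mmhg[1], b$pp_mmhg[1])
  expect_equal(lb$beats, 2)
  # late-activated LV patches are pre-stretched beyond the RV patches
  p <- dplyr::filter(lb$sim$patch, beat == 2)
  pre <- p %>%
    dplyr::left_join(lb$schedule, by = c("patch", "region")) %>%
    dplyr::filter(time_ms - 600 < t_act) %>%
    dplyr::group_by(patch, region) %>%
    dplyr::summarise(prestretch = max(lambda), .groups = "drop")
  late_lv <- dplyr::filter(pre, region == "lv_free")
  rv <- dplyr::filter(pre, region == "rv_free")
  expect_gt(max(late_lv$prestretch), max(rv$prestretch))
})

test_that("resynchronization recovers stroke volume and shortens activation", {
  l <- lbbb_run()$metrics$hemo
  cr <- crt_run()
  expect_gt(cr$metrics$hemo$sv_ml[1], l$sv_ml[1])
  expect_lt(diff(range(cr$schedule$t_act)), diff(range(lbbb_run()$schedule$t_act)))
})

test_that("an oversensitive channel causes premature, unsteady beats", {
  cfg <- heart_config(sac = sac_params(g = 20 * sac_params()[["g"]]))
  run <- run_to_steady_state(cfg, max_beats = 6)
  expect_true(run$premature)
})
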