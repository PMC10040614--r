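rect_loop <- function(offset = 0) {
  # synthetic beat: fill to 60 mL, isovolumetric, eject to 40 mL
  t <- seq(0, 599, by = 1) + offset
  v <- rep(60, 600)
  v[1:100] <- seq(40, 60, length.out = 100)
  v[301:400] <- seq(60, 40, length.out = 100)
  v[401:600] <- 40
  p <- rep(10, 600)
  p[250:400] <- 90
  tibble::tibble(time_ms = t, p_lv = p, v_lv = v, q_mv = 0, q_av = 0,
                 p_rv = p, v_rv = v, q_tv = 0, q_pv = 0)
}

test_that("pressure-volume features recover the synthetic loop", {
  h <- rect_loop()
  ev <- list(inflow_close = 150, outflow_open = 301, outflow_close = 400)
  f <- pv_features(h, "lv", events = ev)
  expect_equal(f$edv_ml, 60)
  expect_equal(f$esv_ml, 40, tolerance = 1e-6)
  expect_equal(f$sv_ml, 20, tolerance = 1e-6)
  expect_equal(f$ivc_ms, 151)
  expect_equal(f$ejection_ms, 99)
})

test_that("max dP/dt matches the closed-form derivative of a sinusoid", {
  t <- seq(0, 599, by = 1)
  h <- tibble::tibble(time_ms = t, p_lv = 50 + 50 * sin(2 * pi * t / 600),
                      v_lv = 50, q_mv = 0, q_av = 0)
  ev <- list(inflow_close = NA, outflow_open = NA, outflow_close = NA)
  f <- pv_features(h, "lv", events = ev)
  expect_equal(f$max_dpdt, 100 * pi / 600, tolerance = 1e-3)
  expect_true(is.na(f$edv_ml) && is.na(f$sv_ml)) # undefined, not fabricated
})

test_that("features are invariant to a common time shift", {
  ev <- list(inflow_close = 150, outflow_open = 301, outflow_close = 400)
  f0 <- pv_features(rect_loop(0), "lv", events = ev)
  ev2 <- lapply(ev, function(x) x + 500)
  f1 <- pv_features(rect_loop(500), "lv", events = ev2)
  expect_equal(f0$sv_ml, f1$sv_ml)
  expect_equal(f0$ivc_ms, f1$ivc_ms)
  expect_equal(f0$max_dpdt, f1$max_dpdt)
})

test_that("patch statistics use interpolated order statistics", {
  tr <- tibble::tibble(patch = rep(1:4, each = 2),
                       lambda = rep(c(1.0, 1.1, 1.2, 1.3), each = 2),
                       tension_kpa = rep(c(10, 20, 30, 40), each = 2))
  ps <- patch_statistics(tr)
  st <- ps[ps$quantity == "max_stretch", ]
  expect_equal(st$median, 1.15)
  expect_equal(st$q1, quantile(c(1, 1.1, 1.2, 1.3), 0.25, names = FALSE))
  expect_equal(st$q3, quantile(c(1, 1.1, 1.2, 1.3), 0.75, names = FALSE))
  # translation equivariance
  tr2 <- dplyr::mutate(tr, lambda = lambda + 0.05)
  st2 <- patch_statistics(tr2)[1, ]
  expect_equal(st2$median, st$median + 0.05)
  expect_equal(st2$q1, st$q1 + 0.05)
  # identical patches collapse the quartiles
  tr3 <- dplyr::mutate(tr, lambda = 1.1, tension_kpa = 25)
  st3 <- patch_statistics(tr3)
  expect_equal(st3$iqr, c(0, 0))
  # fewer than 3 patches: quartiles flagged undefined
  st4 <- patch_statistics(dplyr::filter(tr, patch <= 2))
  expect_true(all(is.na(st4$q1)))
})

test_that("activation summary reports lead time and spread symmetrically", {
  expect_equal(activation_summary(c(130, 132, 131), 130)$lead_ms, 0)
  a <- activation_summary(c(115, 131, 140), 130)
  expect_equal(a$lead_ms, 15)
  expect_equal(a$spread_ms, 25)
  expect_equal(a$n_premature, 1L)
  perm <- activation_summary(c(140, 115, 131), 130)
  expect_equal(a$lead_ms, perm$lead_ms)
  expect_equal(a$spread_ms, perm$spread_ms)
})

test_that("stroke volume from volumes matches the integrated aortic flow", {
  run <- base_run()
  h <- dplyr::filter(run$sim$hemo, beat == max(beat))
  f <- pv_features(h, "lv")
  q_int <- sum(h$q_av) * 1 # 1 ms sampling
  expect_lt(abs(f$sv_ml - q_int) / f$sv_ml, 0.01)
})
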