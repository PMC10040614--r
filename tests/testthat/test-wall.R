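test_that("passive stress is zero at rest, monotone, and matches the energy", {
  expect_equal(passive_fiber_stress(1), 0, tolerance = 1e-14)
  s <- passive_fiber_stress(c(1.05, 1.1, 1.2))
  expect_true(all(diff(s) > 0) && all(s > 0))
  expect_lt(passive_fiber_stress(0.9), 0) # compression resists
  expect_error(passive_fiber_stress(2.5), "lambda")

  # finite-difference oracle along the uniaxial path: sigma = lambda dPsi/dlambda
  p <- passive_params(c_mat = 0.88, bff = 8, bss = 6, bnn = 6, eta = 0)
  psi <- function(l) {
    eff <- (l^2 - 1) / 2
    et <- (1 / l - 1) / 2
    q <- p[["bff"]] * eff^2 + (p[["bss"]] + p[["bnn"]]) * et^2
    p[["c_mat"]] / 2 * (exp(q) - 1)
  }
  for (l in c(0.9, 1.05, 1.1, 1.3)) {
    h <- 1e-6
    fd <- l * (psi(l + h) - psi(l - h)) / (2 * h)
    expect_equal(passive_fiber_stress(l, p), fd, tolerance = 1e-6)
  }
  # analytic derivative against central differences of the stress
  for (l in c(0.95, 1.1)) {
    h <- 1e-6
    fd <- (passive_fiber_stress(l + h, p) - passive_fiber_stress(l - h, p)) / (2 * h)
    expect_equal(cpp_passive_stress_deriv(l, p), fd, tolerance = 1e-5)
  }
})

test_that("identical patches split the sphere symmetrically", {
  vent <- ventricle(aref = rep(8, 6), vwall = rep(5, 6))
  eq <- patch_equilibrium(vent, volume = 40, ta_scale = 10)
  geo <- midwall_geometry(vent, 40)
  expect_equal(eq$lambda, rep(sqrt(geo$area / 48), 6), tolerance = 1e-10)
  expect_equal(sum(eq$area), geo$area, tolerance = 1e-12 * geo$area)
})

test_that("two linearized patches match the closed-form area split", {
  aref <- c(10, 11)
  k <- c(5, 8)
  a_total <- 24
  law <- function(lam, i) k[i] * (lam - 1)
  sol <- cardiomef:::equilibrium_reference(aref, a_total, law)
  # closed form: lam2 = 1 + (k1/k2)(lam1 - 1), areas sum to a_total
  r <- k[1] / k[2]
  poly <- function(l1) aref[1] * l1^2 + aref[2] * (1 + r * (l1 - 1))^2 - a_total
  l1 <- uniroot(poly, c(0.5, 2), tol = 1e-14)$root
  expect_equal(sol$lambda[1], l1, tolerance = 1e-8)
  expect_equal(k[1] * (sol$lambda[1] - 1), k[2] * (sol$lambda[2] - 1),
               tolerance = 1e-8)
})

test_that("compiled solver agrees with the plain-R reference solver", {
  set.seed(42)
  aref <- c(9, 10, 11, 12)
  vwall <- c(4, 5, 5, 6)
  ta <- runif(4, 0, 30)
  pp <- passive_params()
  vent <- ventricle(aref, vwall)
  V <- 45
  geo <- midwall_geometry(vent, V)
  eq <- patch_equilibrium(vent, V, ta_scale = ta, beta0 = 2.3)
  law <- function(lam, i) {
    (passive_fiber_stress(lam, pp) + length_factor(lam, 2.3) * ta[i]) *
      vwall[i] / (aref[i] * lam^2)
  }
  ref <- cardiomef:::equilibrium_reference(aref, geo$area, law, tol = 1e-12)
  expect_equal(eq$lambda, ref$lambda, tolerance = 1e-6)
  expect_equal(attr(eq, "tension"), ref$tension, tolerance = 1e-6)
})

test_that("a stiffer patch takes less stretch at equal tension", {
  aref <- c(10, 10)
  stiff <- c(12, 4)
  law <- function(lam, i) stiff[i] * (lam - 1)
  sol <- cardiomef:::equilibrium_reference(aref, 23, law)
  expect_lt(sol$lambda[1], sol$lambda[2])
})

test_that("solver residuals meet the conservation and equalization bounds", {
  vent <- ventricle(aref = c(6, 7, 8, 9, 10), vwall = c(3, 4, 4, 5, 5))
  pp <- passive_params()
  for (V in c(30, 45, 60)) {
    ta <- c(0, 5, 10, 20, 40)
    eq <- patch_equilibrium(vent, V, ta_scale = ta, beta0 = 2.3, passive = pp)
    geo <- midwall_geometry(vent, V)
    expect_lt(abs(sum(eq$area) - geo$area) / geo$area, 1e-12)
    tens <- (passive_fiber_stress(eq$lambda, pp) +
               length_factor(eq$lambda, 2.3) * ta) * vent$vwall / eq$area
    expect_lt(max(abs(tens - mean(tens))) / abs(mean(tens)), 1e-8)
  }
})

test_that("a single patch reduces to the closed-form sphere", {
  vent <- ventricle(aref = 80, vwall = 30)
  V <- 55
  geo <- midwall_geometry(vent, V)
  eq <- patch_equilibrium(vent, V, ta_scale = 12, beta0 = 2.3)
  lam <- sqrt(geo$area / 80)
  expect_equal(eq$lambda, lam, tolerance = 1e-12)
  sigma <- passive_fiber_stress(lam) + length_factor(lam, 2.3) * 12
  t_hand <- sigma * 30 / geo$area
  expect_equal(attr(eq, "tension"), t_hand, tolerance = 1e-10)
  expect_equal(cavity_pressure(vent, V, t_hand),
               7.50061683 * 2 * t_hand / geo$radius, tolerance = 1e-12)
})

test_that("Laplace closure is linear in tension and zero at zero", {
  vent <- ventricle(aref = 80, vwall = 30)
  expect_equal(cavity_pressure(vent, 50, 0), 0)
  expect_equal(cavity_pressure(vent, 50, 8), 2 * cavity_pressure(vent, 50, 4),
               tolerance = 1e-12)
  # hand evaluation: r = 2 cm sphere (V chosen to give it), T = 3 kPa cm
  v_target <- 4 / 3 * pi * 8 - 15 # cavity volume giving midwall r = 2
  expect_equal(cavity_pressure(ventricle(80, 30), v_target, 3),
               7.50061683 * 2 * 3 / 2, tolerance = 1e-10)
  expect_error(midwall_geometry(ventricle(80, 30, v0 = 10), 5), "dead volume")
})
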