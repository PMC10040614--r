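#' Passive fiber stress
#'
#' Cauchy stress along the fiber axis of the orthotropic exponential
#' material under incompressible uniaxial kinematics: axial strain
#' `E_ff = (lambda^2 - 1)/2`, transverse stretches `lambda^(-1/2)`, shears
#' zero, and the transverse normal stress eliminated by the thin-wall
#' zero-traction condition, giving `sigma = lambda dPsi/dlambda` with the
#' analytic derivative. Vectorised over `lambda`.
#'
#' @param lambda stretch ratio in (0.5, 2).
#' @param params material parameters from [passive_params()].
#' @return fiber Cauchy stress (kPa); zero at `lambda = 1`, negative in
#'   compression.
#' @export
passive_fiber_stress <- function(lambda, params = passive_params()) {
  if (any(lambda <= 0.5 | lambda >= 2)) abort("lambda must lie in (0.5, 2)")
  vapply(lambda, cpp_passive_stress, numeric(1), params = params)
}

#' Define a thin-wall multi-patch ventricle
#'
#' A ventricle is a thin-wall sphere partitioned into wall patches, each
#' with a reference midwall area and wall volume. Cavity volume sets the
#' midwall sphere; the equilibrium solve distributes the sphere's area over
#' the patches such that all carry the same membrane tension.
#'
#' @param aref per-patch reference midwall areas (cm^2).
#' @param vwall per-patch wall volumes (mL).
#' @param v0 dead volume (mL); cavity volumes at or below `v0` are invalid.
#' @return a list of class `cardiomef_ventricle`.
#' @export
ventricle <- function(aref, vwall, v0 = 0) {
  if (length(aref) != length(vwall)) abort("aref and vwall lengths differ")
  if (any(aref <= 0) || any(vwall <= 0)) abort("areas and wall volumes must be positive")
  structure(list(aref = as.numeric(aref), vwall = as.numeric(vwall), v0 = v0),
            class = "cardiomef_ventricle")
}

#' Midwall sphere geometry at a cavity volume
#'
#' The midwall encloses the cavity plus half the wall: returns radius (cm)
#' and midwall area (cm^2).
#'
#' @param vent a [ventricle()].
#' @param volume cavity volume (mL).
#' @return a list with `radius` and `area`.
#' @export
midwall_geometry <- function(vent, volume) {
  if (volume <= vent$v0) abort("cavity volume must exceed the dead volume")
  vm <- volume + 0.5 * sum(vent$vwall)
  r <- (3 * vm / (4 * pi))^(1 / 3)
  list(radius = r, area = 4 * pi * r^2)
}

#' Patch equilibrium at a prescribed cavity volume
#'
#' Solves for per-patch areas summing to the midwall sphere area with a
#' common membrane tension `T_i = sigma_i h_i` across patches, where
#' `sigma_i` is passive plus active fiber stress at the patch stretch
#' `lambda_i = sqrt(A_i / A_ref,i)` and `h_i = Vwall_i / A_i` the current
#' wall thickness. Newton iteration with step damping; at most 50
#' iterations.
#'
#' @param vent a [ventricle()].
#' @param volume cavity volume (mL), greater than the dead volume.
#' @param ta_scale per-patch active-tension magnitude before the length
#'   factor (kPa): `Tref/rs ((zeta_s+1) S + zeta_w W)`; zero for a passive
#'   wall.
#' @param passive material parameters from [passive_params()].
#' @param beta0 length-dependence coefficient applied inside the solve
#'   (0 disables the length factor).
#' @param warm_areas optional starting areas.
#' @return a tibble with one row per patch (`patch`, `area`, `lambda`,
#'   `tension`) and attributes `tension` (common membrane tension, kPa cm)
#'   and `iterations`.
#' @export
patch_equilibrium <- function(vent, volume, ta_scale = 0,
                              passive = passive_params(), beta0 = 0,
                              warm_areas = NULL) {
  geo <- midwall_geometry(vent, volume)
  n <- length(vent$aref)
  ta_scale <- rep_len(ta_scale, n)
  warm <- if (is.null(warm_areas)) numeric(0) else warm_areas
  sol <- cpp_patch_equilibrium(vent$aref, vent$vwall, ta_scale, beta0,
                               passive, geo$area, warm)
  out <- tibble(patch = seq_len(n), area = sol$areas, lambda = sol$lambda,
                tension = sol$tension)
  attr(out, "tension") <- sol$tension
  attr(out, "iterations") <- sol$iterations
  out
}

#' Cavity pressure from wall tension (Laplace closure)
#'
#' `P = 2 T / r` for a thin-wall sphere, with the midwall radius from the
#' cavity volume; tension in kPa cm and radius in cm give kPa, converted to
#' mmHg.
#'
#' @param vent a [ventricle()].
#' @param volume cavity volume (mL).
#' @param tension membrane tension (kPa cm).
#' @return pressure (mmHg).
#' @export
cavity_pressure <- function(vent, volume, tension) {
  geo <- midwall_geometry(vent, volume)
  7.50061683 * 2 * tension / geo$radius
}

# Reference equilibrium solver in plain R with a pluggable tension law,
# used as the independent oracle for the compiled solver. `tension_fun`
# maps (lambda, patch index) -> membrane tension.
equilibrium_reference <- function(aref, a_total, tension_fun,
                                  tol = 1e-12, maxit = 200) {
  n <- length(aref)
  areas <- aref * a_total / sum(aref)
  for (it in seq_len(maxit)) {
    lam <- sqrt(areas / aref)
    tens <- vapply(seq_len(n), function(i) tension_fun(lam[i], i), numeric(1))
    eps <- 1e-7
    dtda <- vapply(seq_len(n), function(i) {
      lp <- sqrt((areas[i] + eps) / aref[i])
      (tension_fun(lp, i) - tens[i]) / eps
    }, numeric(1))
    dtda <- pmax(dtda, 1e-10)
    tstar <- sum(tens / dtda) / sum(1 / dtda)
    step <- (tstar - tens) / dtda
    areas <- areas + step
    areas <- areas * a_total / sum(areas)
    if (max(abs(tens - mean(tens))) <= tol * max(1e-9, abs(mean(tens)))) break
  }
  lam <- sqrt(areas / aref)
  tens <- vapply(seq_len(n), function(i) tension_fun(lam[i], i), numeric(1))
  list(areas = areas, lambda = lam, tension = mean(tens), iterations = it)
}
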