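#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a heart simulation
#'
#' One row per beat and ventricle with the pressure-volume features of
#' [pv_features()].
#'
#' @param x a `cardiomef_sim`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cardiomef_sim <- function(x, ...) {
  purrr::map_df(sort(unique(x$hemo$beat)), function(b) {
    m <- beat_metrics(x, b)$hemo
    mutate(m, beat = b, .before = 1)
  })
}

#' @rdname tidy.cardiomef_sim
#' @export
tidy.cardiomef_run <- function(x, ...) {
  x$per_beat
}

#' One-row summary of a heart run
#'
#' Final-beat left-ventricular features plus convergence information.
#'
#' @param x a `cardiomef_run` (or `cardiomef_sim`).
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.cardiomef_run <- function(x, ...) {
  m <- beat_metrics(x$sim)
  lv <- m$hemo[m$hemo$side == "lv", ]
  tibble(beats = x$beats, converged = x$converged, premature = x$premature,
         sv_ml = lv$sv_ml, edv_ml = lv$edv_ml, esv_ml = lv$esv_ml,
         edp_mmhg = lv$edp_mmhg, pp_mmhg = lv$pp_mmhg,
         max_dpdt = lv$max_dpdt, ivc_ms = lv$ivc_ms,
         ejection_ms = lv$ejection_ms)
}

#' @rdname glance.cardiomef_run
#' @export
glance.cardiomef_sim <- function(x, ...) {
  m <- beat_metrics(x)
  lv <- m$hemo[m$hemo$side == "lv", ]
  tibble(beats = x$n_beats, sv_ml = lv$sv_ml, edv_ml = lv$edv_ml,
         esv_ml = lv$esv_ml, edp_mmhg = lv$edp_mmhg, pp_mmhg = lv$pp_mmhg,
         max_dpdt = lv$max_dpdt, ivc_ms = lv$ivc_ms,
         ejection_ms = lv$ejection_ms)
}
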