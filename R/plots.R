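#' Pressure-volume loop plot
#'
#' Plots the ventricular PV loops of a simulation (one path per beat).
#' A healthy loop is traversed counterclockwise in the (V, P) plane.
#'
#' @param sim a `cardiomef_sim`.
#' @param sides which ventricles to draw.
#' @return a ggplot object.
#' @export
plot_pv_loop <- function(sim, sides = c("lv", "rv")) {
  h <- sim$hemo
  long <- bind_rows(
    if ("lv" %in% sides)
      tibble(side = "LV", beat = h$beat, p = h$p_lv, v = h$v_lv),
    if ("rv" %in% sides)
      tibble(side = "RV", beat = h$beat, p = h$p_rv, v = h$v_rv))
  ggplot2::ggplot(long, ggplot2::aes(.data$v, .data$p, colour = .data$side,
                                     group = interaction(.data$side, .data$beat))) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::labs(x = "Volume (mL)", y = "Pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-patch trace plot
#'
#' Stretch, active tension, or membrane potential of every wall patch over
#' time, coloured by region.
#'
#' @param sim a `cardiomef_sim`.
#' @param what one of `"lambda"`, `"tension_kpa"`, `"vm_mv"`, `"cai_mm"`.
#' @return a ggplot object.
#' @export
plot_patch_traces <- function(sim, what = c("lambda", "tension_kpa",
                                            "vm_mv", "cai_mm")) {
  what <- match.arg(what)
  p <- sim$patch
  ggplot2::ggplot(p, ggplot2::aes(.data$time_ms, .data[[what]],
                                  group = .data$patch,
                                  colour = .data$region)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (ms)", y = what, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.cardiomef_sim <- function(object, type = c("pv", "patch"), ...) {
  type <- match.arg(type)
  if (type == "pv") plot_pv_loop(object, ...) else plot_patch_traces(object, ...)
}

#' @export
autoplot.cardiomef_run <- function(object, ...) {
  autoplot(object$sim, ...)
}
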