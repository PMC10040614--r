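#' Valve events of one beat
#'
#' Locates, by linear interpolation of threshold crossings of the valve
#' flows, the inflow-valve (mitral/tricuspid) closure, outflow-valve
#' (aortic/pulmonary) opening and closure of a single-beat hemodynamic
#' trace.
#'
#' @param hemo single-beat hemodynamic tibble (from [simulate_heart()]).
#' @param side `"lv"` or `"rv"`.
#' @param q_eps flow threshold separating open from closed (mL/ms).
#' @return list with `inflow_close`, `outflow_open`, `outflow_close` (ms,
#'   `NA` when the event is absent).
#' @export
valve_events <- function(hemo, side = c("lv", "rv"), q_eps = 1e-3) {
  side <- match.arg(side)
  t <- hemo$time_ms
  q_in <- if (side == "lv") hemo$q_mv else hemo$q_tv
  q_out <- if (side == "lv") hemo$q_av else hemo$q_pv

  cross_down <- function(q, from = -Inf, to = Inf) {
    i <- which(q[-length(q)] > q_eps & q[-1] <= q_eps &
                 t[-length(t)] >= from & t[-1] <= to)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    t[i] + (q[i] - q_eps) / (q[i] - q[i + 1]) * (t[i + 1] - t[i])
  }
  cross_up <- function(q, from = -Inf) {
    i <- which(q[-length(q)] <= q_eps & q[-1] > q_eps & t[-length(t)] >= from)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    t[i] + (q_eps - q[i]) / (q[i + 1] - q[i]) * (t[i + 1] - t[i])
  }

  out_open <- cross_up(q_out)
  # inflow closure: last closure of the inflow valve before outflow opening
  in_close <- NA_real_
  if (!is.na(out_open)) {
    idx <- which(q_in[-length(q_in)] > q_eps & q_in[-1] <= q_eps &
                   t[-1] <= out_open)
    if (length(idx)) {
      i <- idx[length(idx)]
      in_close <- t[i] + (q_in[i] - q_eps) / (q_in[i] - q_in[i + 1]) *
        (t[i + 1] - t[i])
    }
  } else {
    in_close <- cross_down(q_in)
  }
  out_close <- if (is.na(out_open)) NA_real_ else {
    # end of the contiguous ejection region that starts at out_open
    cross_down(q_out, from = out_open)
  }
  list(inflow_close = in_close, outflow_open = out_open,
       outflow_close = out_close)
}

#' Pressure-volume features of one beat
#'
#' End-diastolic volume and pressure at inflow-valve closure, end-systolic
#' volume at outflow-valve closure, stroke volume, peak pressure, maximal
#' dP/dt (central differences), and the isovolumetric-contraction and
#' ejection durations. Events missing from the trace yield `NA` features
#' rather than fabricated values.
#'
#' @param hemo single-beat hemodynamic tibble with columns `time_ms`,
#'   pressure and volume columns for the requested side, and valve flow
#'   columns (for event detection).
#' @param side `"lv"` or `"rv"`.
#' @param events optional list as returned by [valve_events()]; computed
#'   from the flows when `NULL`.
#' @return one-row tibble: `side`, `edv_ml`, `esv_ml`, `sv_ml`, `edp_mmhg`,
#'   `pp_mmhg`, `max_dpdt`, `ivc_ms`, `ejection_ms`.
#' @export
pv_features <- function(hemo, side = c("lv", "rv"), events = NULL) {
  side <- match.arg(side)
  t <- hemo$time_ms
  p <- if (side == "lv") hemo$p_lv else hemo$p_rv
  v <- if (side == "lv") hemo$v_lv else hemo$v_rv
  if (is.null(events)) events <- valve_events(hemo, side)

  at <- function(x, when) {
    if (is.na(when)) return(NA_real_)
    approx(t, x, xout = when, rule = 2)$y
  }
  edv <- at(v, events$inflow_close)
  esv <- at(v, events$outflow_close)
  edp <- at(p, events$inflow_close)
  dpdt <- if (length(t) > 2) {
    max(diff(p, lag = 2) / diff(t, lag = 2))
  } else NA_real_
  ivc <- events$outflow_open - events$inflow_close
  ej <- events$outflow_close - events$outflow_open
  tibble(side = side, edv_ml = edv, esv_ml = esv, sv_ml = edv - esv,
         edp_mmhg = edp, pp_mmhg = max(p), max_dpdt = dpdt,
         ivc_ms = ivc, ejection_ms = ej)
}

#' Per-patch stretch and tension statistics
#'
#' Per-patch maxima of stretch and active tension over a beat, summarised
#' across patches as the median and first/third quartiles (linear
#' interpolation between order statistics).
#'
#' @param patch_trace per-patch trace tibble (columns `patch`, `lambda`,
#'   `tension_kpa`), typically one beat.
#' @return a tibble with columns `quantity` (`max_stretch`, `max_tension`),
#'   `median`, `q1`, `q3`, `iqr`, `n_patches`; quartiles are `NA` with
#'   fewer than 3 patches.
#' @export
patch_statistics <- function(patch_trace) {
  per <- patch_trace %>%
    group_by(.data$patch) %>%
    summarise(max_stretch = max(.data$lambda),
              max_tension = max(.data$tension_kpa), .groups = "drop")
  n <- nrow(per)
  one <- function(x, nm) {
    if (n >= 3) {
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    } else {
      q <- c(NA_real_, median(x), NA_real_)
    }
    tibble(quantity = nm, median = q[2], q1 = q[1], q3 = q[3],
           iqr = q[3] - q[1], n_patches = n)
  }
  bind_rows(one(per$max_stretch, "max_stretch"),
            one(per$max_tension, "max_tension"))
}

#' Activation summary
#'
#' Earliest pre-stimulus depolarization lead time and the activation
#' spread, from per-patch depolarization times and the stimulus schedule.
#' Both summaries are invariant to patch order.
#'
#' @param t_dep per-patch depolarization times (ms).
#' @param t_stim per-patch stimulus times (ms), recycled if scalar.
#' @return a tibble: `lead_ms` (`max(0, stimulus - earliest t_dep)` over
#'   patches), `spread_ms` (`max(t_dep) - min(t_dep)`), `n_premature`.
#' @export
activation_summary <- function(t_dep, t_stim) {
  t_stim <- rep_len(t_stim, length(t_dep))
  ok <- !is.na(t_dep)
  lead <- if (any(ok)) max(0, max(t_stim[ok] - t_dep[ok])) else 0
  spread <- if (any(ok)) max(t_dep[ok]) - min(t_dep[ok]) else NA_real_
  tibble(lead_ms = lead, spread_ms = spread,
         n_premature = sum(t_dep[ok] < t_stim[ok] - 1e-9))
}

#' Beat metrics of a simulation
#'
#' Hemodynamic features for both ventricles plus per-patch summaries for a
#' chosen beat of a [simulate_heart()] result.
#'
#' @param sim a `cardiomef_sim`.
#' @param beat beat number; defaults to the last.
#' @return a list: `hemo` (two-row tibble from [pv_features()]), `patches`
#'   (from [patch_statistics()]), `activation` (from
#'   [activation_summary()]), `events` (per-side valve events).
#' @export
beat_metrics <- function(sim, beat = NULL) {
  if (is.null(beat)) beat <- max(sim$hemo$beat)
  h <- dplyr::filter(sim$hemo, .data$beat == !!beat, .data$time_ms > min(.data$time_ms))
  p <- dplyr::filter(sim$patch, .data$beat == !!beat)
  ev_lv <- valve_events(h, "lv")
  ev_rv <- valve_events(h, "rv")
  t0 <- (beat - 1) * sim$config$timing[["cycle_length"]]
  tdep <- p %>%
    group_by(.data$patch) %>%
    summarise(t_dep = detect_activation_time(
      data.frame(time_ms = .data$time_ms - t0, vm_mv = .data$vm_mv), 0),
      .groups = "drop")
  act <- activation_summary(tdep$t_dep, sim$config$patches$t_act)
  list(hemo = bind_rows(pv_features(h, "lv", ev_lv), pv_features(h, "rv", ev_rv)),
       patches = patch_statistics(p),
       activation = act,
       t_dep = tdep,
       events = list(lv = ev_lv, rv = ev_rv))
}
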