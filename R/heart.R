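#' Default wall partition of the biventricular surrogate
#'
#' Twelve left-ventricular patches (eight free-wall, four septal - septal
#' patches are carried by the LV sphere) and six right-ventricular patches.
#' Reference areas and wall volumes are split evenly within each ventricle;
#' two LV free-wall patches and one apical RV patch are tagged as the
#' resynchronization pacing sites.
#'
#' @param n_lv_free,n_septal,n_rv patch counts per region.
#' @param aref_lv,aref_rv total reference midwall areas (cm^2).
#' @param vwall_lv,vwall_rv total wall volumes (mL); septal wall volume is
#'   part of `vwall_lv`.
#' @param t_act activation time applied to every patch (ms).
#' @return a tibble with columns `patch`, `ventricle`, `region`,
#'   `pace_crt`, `aref`, `vwall`, `t_act`.
#' @export
default_patches <- function(n_lv_free = 8, n_septal = 4, n_rv = 6,
                            aref_lv = 79.4, aref_rv = 79,
                            vwall_lv = 34, vwall_rv = 13, t_act = 130) {
  n_lv <- n_lv_free + n_septal
  region <- c(rep("lv_free", n_lv_free), rep("septum", n_septal),
              rep("rv_free", n_rv))
  vent <- c(rep("lv", n_lv), rep("rv", n_rv))
  aref <- c(rep(aref_lv / n_lv, n_lv), rep(aref_rv / n_rv, n_rv))
  vwall <- c(rep(vwall_lv / n_lv, n_lv), rep(vwall_rv / n_rv, n_rv))
  pace <- rep(FALSE, length(vent))
  pace[c(1, min(2, n_lv_free))] <- TRUE            # LV epicardial lead region
  pace[n_lv + n_rv] <- TRUE                        # RV apical lead region
  tibble(patch = seq_along(vent), ventricle = vent, region = region,
         pace_crt = pace, aref = aref, vwall = vwall,
         t_act = rep(t_act, length(vent)))
}

#' Assemble a closed-loop heart configuration
#'
#' Bundles cell, channel, tension, passive-material and circulation
#' parameters with the wall partition, MEF toggles and timing into the
#' configuration consumed by [simulate_heart()] and the protocol
#' pipelines. Defaults are the package's calibrated baseline (600 ms cycle,
#' 130 ms atrioventricular delay, simultaneous ventricular activation).
#'
#' @param cell_type transmural cell type used by all patches.
#' @param sac,land,passive,circ,toggles component parameter sets.
#' @param cycle_length,av_delay timing (ms); all patches activate at
#'   `av_delay` unless `patches` overrides.
#' @param patches wall partition tibble; defaults to [default_patches()].
#' @param tref_override optional replacement for the tension scale `tref`
#'   (used by the ablation experiments that remove velocity dependence).
#' @param n_patches_lv,n_septal,n_patches_rv patch counts forwarded to
#'   [default_patches()].
#' @param init named vector of initial compartment volumes (mL).
#' @param dt_mech mechanics step (ms); electrophysiology substeps at
#'   `dt_mech / ep_substeps`, tension every `tension_every` EP substeps,
#'   circulation at `dt_mech / circ_substeps`.
#' @param ep_substeps,tension_every,circ_substeps,stim_dur,stim_amp
#'   integration and stimulus settings.
#' @return a list of class `cardiomef_config`.
#' @export
heart_config <- function(cell_type = "epi", sac = sac_params(),
                         land = land_params(), passive = passive_params(),
                         circ = circ_params(), toggles = mef_toggles(),
                         cycle_length = 600, av_delay = 130,
                         patches = NULL, tref_override = NULL,
                         n_patches_lv = 8, n_septal = 4, n_patches_rv = 6,
                         init = NULL,
                         dt_mech = 0.2, ep_substeps = 10, tension_every = 5,
                         circ_substeps = 2, stim_dur = 2, stim_amp = -36) {
  if (is.null(patches))
    patches <- default_patches(n_lv_free = n_patches_lv, n_septal = n_septal,
                               n_rv = n_patches_rv, t_act = av_delay)
  if (!is.null(tref_override)) land[["tref"]] <- tref_override
  init_def <- c(v_sa = 127.0, v_sv = 140.9, v_pa = 81.5, v_pv = 136.5,
                v_ra = 11.4, v_la = 77.4, v_lv = 55.1, v_rv = 58.4)
  if (!is.null(init)) init_def[names(init)] <- init
  structure(list(
    cell = cell_params(cell_type),
    sac = sac, land = land, passive = passive, circ = circ,
    toggles = toggles, patches = patches,
    timing = c(cycle_length = cycle_length, av_delay = av_delay,
               dt_mech = dt_mech, ep_substeps = ep_substeps,
               tension_every = tension_every, circ_substeps = circ_substeps,
               stim_dur = stim_dur, stim_amp = stim_amp),
    init = init_def
  ), class = "cardiomef_config")
}

#' Initial coupled state for a configuration
#'
#' Cells are paced to steady state in isolation (ignoring stretch) and
#' replicated over the patches; the cross-bridge states start at their
#' diastolic equilibrium; compartment volumes come from the
#' configuration's initial volumes; valve flows start at zero.
#'
#' @param config a [heart_config()].
#' @return a state list consumed by [simulate_heart()].
#' @export
initial_heart_state <- function(config) {
  cl <- config$timing[["cycle_length"]]
  paced <- paced_state_cached(config$cell, cl)
  np <- nrow(config$patches)
  cells <- matrix(paced, nrow = length(paced), ncol = np)
  land0 <- land_state(config$land, cai_diastolic = paced[["Cai"]])
  land <- matrix(land0, nrow = length(land0), ncol = np)
  circ <- c(config$init[c("v_sa", "v_sv", "v_pa", "v_pv", "v_ra", "v_la",
                          "v_lv", "v_rv")],
            q_mv = 0, q_av = 0, q_tv = 0, q_pv = 0)
  list(cells = cells, land = land, circ = circ,
       lambda = rep(1, np), areas = config$patches$aref,
       p_lv = 5, p_rv = 3)
}

engine_config <- function(config) {
  list(cell = config$cell, sac = config$sac, land = config$land,
       passive = config$passive, circ = config$circ,
       toggles = config$toggles,
       timing = config$timing,
       patches = list(
         ventricle = as.integer(config$patches$ventricle == "rv"),
         aref = config$patches$aref,
         vwall = config$patches$vwall,
         t_act = config$patches$t_act))
}

#' Simulate the coupled heart
#'
#' Runs the strongly coupled electromechanics-circulation loop for a number
#' of beats: per mechanics step, a fixed-point iteration between cavity
#' pressure (multi-patch wall equilibrium) and the circulation flows,
#' followed by staggered electrophysiology and tension substeps with the
#' stretch-activated current fed by the patch stretches.
#'
#' @param config a [heart_config()].
#' @param n_beats number of cycles to simulate.
#' @param state starting state; a fresh [initial_heart_state()] when
#'   `NULL`.
#' @param record_every trace sampling interval (ms).
#' @return an object of class `cardiomef_sim`: list with `hemo` and
#'   `patch` tibbles, the final `state`, the `config` and coupling
#'   diagnostics.
#' @export
#' @examples
#' \donttest{
#' fix <- make_fixture("mini-heart")
#' sim <- simulate_heart(fix$config, n_beats = 1)
#' dplyr::last(sim$hemo$v_lv)
#' }
simulate_heart <- function(config, n_beats = 1, state = NULL,
                           record_every = 1) {
  if (is.null(state)) state <- initial_heart_state(config)
  out <- cpp_run_heart(engine_config(config), state, as.integer(n_beats),
                       record_every)
  hemo <- as_tibble(as.data.frame(out$hemo))
  patch <- as_tibble(as.data.frame(out$patch)) %>%
    left_join(config$patches[c("patch", "ventricle", "region")], by = "patch")
  structure(list(hemo = hemo, patch = patch, state = out$state,
                 config = config, n_beats = n_beats,
                 fp_converged = out$fp_converged,
                 max_fp_iterations = out$max_fp_iterations),
            class = "cardiomef_sim")
}

#' @export
print.cardiomef_sim <- function(x, ...) {
  cat("<cardiomef_sim>", x$n_beats, "beat(s),",
      nrow(x$config$patches), "patches\n")
  m <- try(beat_metrics(x), silent = TRUE)
  if (!inherits(m, "try-error")) {
    h <- m$hemo
    cat(sprintf("  LV: EDV %.1f mL, SV %.1f mL, PP %.1f mmHg\n",
                h$edv_ml[1], h$sv_ml[1], h$pp_mmhg[1]))
    cat(sprintf("  RV: EDV %.1f mL, SV %.1f mL, PP %.1f mmHg\n",
                h$edv_ml[2], h$sv_ml[2], h$pp_mmhg[2]))
  }
  invisible(x)
}

#' Run a configuration to its periodic steady state
#'
#' Repeats beats until the beat-to-beat relative changes of LV stroke
#' volume, end-diastolic volume and end-diastolic pressure all drop below
#' the tolerance, or the beat budget is exhausted. Non-convergence (as
#' arises under strongly premature stretch-triggered activity) is reported
#' in the result, not raised as an error.
#'
#' @param config a [heart_config()].
#' @param max_beats beat budget.
#' @param tol relative beat-to-beat tolerance.
#' @param state optional starting state.
#' @param record_every trace sampling (ms).
#' @param min_beats minimum number of beats to simulate even after the
#'   tolerance is met (used by paired experiments that compare metrics at
#'   a common beat).
#' @return a list of class `cardiomef_run`: `sim` (final beat), `state`,
#'   `per_beat` (tibble of per-beat LV/RV features), `converged`, `beats`,
#'   `premature` (any depolarization ahead of its stimulus), `config`.
#' @export
run_to_steady_state <- function(config, max_beats = 10, tol = 0.01,
                                state = NULL, record_every = 1,
                                min_beats = 1) {
  if (is.null(state)) state <- initial_heart_state(config)
  prev <- NULL
  rows <- list()
  converged <- FALSE
  premature <- FALSE
  sim <- NULL
  b <- 0
  while (b < max_beats) {
    b <- b + 1
    sim <- simulate_heart(config, 1, state, record_every)
    state <- sim$state
    m <- beat_metrics(sim)
    lv <- m$hemo[m$hemo$side == "lv", ]
    rows[[b]] <- mutate(m$hemo, beat = b)
    if (m$activation$n_premature > 0) premature <- TRUE
    if (!is.null(prev) &&
        all(is.finite(c(lv$sv_ml, lv$edv_ml, lv$edp_mmhg,
                        prev$sv_ml, prev$edv_ml, prev$edp_mmhg)))) {
      rel <- function(a, p) abs(a - p) / max(abs(p), 1e-9)
      if (rel(lv$sv_ml, prev$sv_ml) < tol &&
          rel(lv$edv_ml, prev$edv_ml) < tol &&
          rel(lv$edp_mmhg, prev$edp_mmhg) < tol) {
        converged <- TRUE
        if (b >= min_beats) break
      }
    }
    prev <- lv
  }
  structure(list(sim = sim, state = state,
                 per_beat = bind_rows(rows), converged = converged,
                 beats = b, premature = premature, config = config),
            class = "cardiomef_run")
}

#' @export
print.cardiomef_run <- function(x, ...) {
  cat("<cardiomef_run>", x$beats, "beat(s), converged:", x$converged,
      if (x$premature) "(premature activity)" else "", "\n")
  print(x$sim)
  invisible(x)
}
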