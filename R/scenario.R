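#' Scenario specification
#'
#' Describes one hemorrhage/resuscitation test scenario: the infusate, the
#' initial hemorrhage severity, whether coagulation operates, the scripted
#' events, an optional vasopressor bolus, and the termination rule.
#'
#' The four shipped scenarios (see [default_scenarios()]) are: (1) an
#' initial bleed resuscitated with whole blood under active coagulation;
#' (2) a sudden massive re-bleed (tourniquet failure) resuscitated with
#' whole blood; (3) the same re-bleed with a 15 mmHg vasopressor bolus
#' applied immediately after it and withdrawn 10 min later; and (4) a
#' re-bleed followed by an ongoing non-clotting (coagulopathic) hemorrhage
#' resuscitated with crystalloid, capped at 30 min.
#'
#' @param id Integer scenario id.
#' @param infusate `"whole_blood"` or `"crystalloid"`.
#' @param hf_init `"high"`, `"low"` (resolved against the outflow config) or
#'   a numeric hemorrhage factor in mL/min per mmHg.
#' @param coag_enabled Does coagulation decay the hemorrhage factor?
#' @param open_with_rebleed Start with the massive-hemorrhage event?
#' @param rebleed_release_map Sensed MAP (mmHg) at which the massive event
#'   releases.
#' @param rebleed_max_min Maximum duration of the massive event, minutes:
#'   the event also releases once this time has elapsed, covering the case
#'   where the controller counteracts the bleed strongly enough that the
#'   release pressure is never reached.
#' @param after_release `"none"` or `"ramp_to_cap"` (non-clotting bleed
#'   started once the opening re-bleed has run its course).
#' @param hf_cap User-defined hemorrhage-factor limit for `ramp_to_cap`.
#' @param hf_ramp_rate Escalation rate of the non-clotting bleed,
#'   (mL/min/mmHg) per minute; `NA` uses the outflow config's over-pressure
#'   escalation rate.
#' @param vasopressor `NULL`, or `list(step = mmHg, duration_min = minutes)`
#'   applied immediately after the opening re-bleed releases.
#' @param termination `list(type = "stabilize", target_fraction, stabilize_min)`
#'   (done once the sensed MAP has first reached `target_fraction` of the
#'   target and `stabilize_min` further minutes have elapsed) or
#'   `list(type = "time_cap", time_cap_min)`.
#' @export
scenario_spec <- function(id, infusate = c("whole_blood", "crystalloid"),
                          hf_init = "high", coag_enabled = TRUE,
                          open_with_rebleed = FALSE,
                          rebleed_release_map = 40, rebleed_max_min = 10,
                          after_release = c("none", "ramp_to_cap"),
                          hf_cap = NA_real_, hf_ramp_rate = NA_real_,
                          vasopressor = NULL,
                          termination = list(type = "stabilize",
                                             target_fraction = 0.99,
                                             stabilize_min = 15)) {
  infusate <- match.arg(infusate)
  after_release <- match.arg(after_release)
  if (!termination$type %in% c("stabilize", "time_cap")) {
    stop("termination$type must be 'stabilize' or 'time_cap'", call. = FALSE)
  }
  if (after_release == "ramp_to_cap" && (is.null(hf_cap) || is.na(hf_cap))) {
    stop("a ramp_to_cap scenario requires an explicit hf_cap", call. = FALSE)
  }
  if (!is.null(vasopressor)) {
    stopifnot(is.list(vasopressor), vasopressor$step > 0,
              vasopressor$duration_min > 0)
  }
  structure(list(id = id, infusate = infusate, hf_init = hf_init,
                 coag_enabled = isTRUE(coag_enabled),
                 open_with_rebleed = isTRUE(open_with_rebleed),
                 rebleed_release_map = rebleed_release_map,
                 rebleed_max_min = rebleed_max_min,
                 after_release = after_release, hf_cap = hf_cap,
                 hf_ramp_rate = hf_ramp_rate,
                 vasopressor = vasopressor, termination = termination),
            class = "scenario_spec")
}

#' The four chained default scenarios
#'
#' @param severity `"low"` or `"high"` overall bleed severity. Severity
#'   selects the initial hemorrhage factor for scenarios 1-3 (60 vs 120
#'   mL/min at a MAP of 68 mmHg) and the base/cap of the continuous
#'   non-clotting bleed in scenario 4. The low-severity bleed ramps from
#'   0.4 to 0.5 mL/min per mmHg at the over-pressure escalation rate (a
#'   bleed the controller can outrun). The high-severity bleed ramps from
#'   2.5 at 0.6 per minute toward a ceiling of 17: within the window the
#'   hemorrhage comes to exceed the infusion pump's maximum rate at any
#'   attainable pressure, the defining feature of an exsanguinating
#'   coagulopathic bleed that no infusion-only controller can arrest.
#' @return List of four [scenario_spec()]s.
#' @export
default_scenarios <- function(severity = c("low", "high")) {
  severity <- match.arg(severity)
  s4_base <- if (severity == "high") 2.5 else 0.4
  s4_cap <- if (severity == "high") 17 else 0.5
  s4_ramp <- if (severity == "high") 0.6 else NA_real_
  list(
    scenario_spec(1, "whole_blood", hf_init = severity),
    scenario_spec(2, "whole_blood", hf_init = severity,
                  open_with_rebleed = TRUE),
    scenario_spec(3, "whole_blood", hf_init = severity,
                  open_with_rebleed = TRUE,
                  vasopressor = list(step = 15, duration_min = 10)),
    scenario_spec(4, "crystalloid", hf_init = s4_base, coag_enabled = FALSE,
                  open_with_rebleed = TRUE, after_release = "ramp_to_cap",
                  hf_cap = s4_cap, hf_ramp_rate = s4_ramp,
                  termination = list(type = "time_cap", time_cap_min = 30))
  )
}

#' Initialize a run
#'
#' Sets the whole-blood vessel as active and fills it so the sensed MAP is
#' the configured starting pressure, with the whole-system volume deficit
#' ledger initialized (the hemorrhagic-shock starting condition: 40 mmHg
#' with roughly 2300 mL lost).
#'
#' @param profile Whole-blood [vessel_profile()].
#' @param start_map Starting MAP, mmHg.
#' @param deficit_mL Initial whole-system volume deficit, mL.
#' @param pressure_offset Static elevation offset of the loop, mmHg.
#' @param vasopressor_step Step magnitude when the resistance branch is
#'   engaged, mmHg.
#' @return A [plant_state()] carrying a `deficit_mL` field.
#' @export
initialize_run <- function(profile, start_map = 40, deficit_mL = 2300,
                           pressure_offset = 0, vasopressor_step = 15) {
  p_vessel <- start_map - pressure_offset
  if (p_vessel < 0 || p_vessel > vessel_max_pressure(profile)) {
    stop(sprintf(
      "start pressure %.1f mmHg is unreachable (vessel supplies 0-%.1f mmHg)",
      start_map, vessel_max_pressure(profile) + pressure_offset),
      call. = FALSE)
  }
  st <- plant_state(profile,
                    volume = volume_at_pressure(profile, p_vessel),
                    pressure_offset = pressure_offset,
                    vasopressor_step = vasopressor_step)
  st$deficit_mL <- deficit_mL
  st
}

#' Termination check
#'
#' Applies the scenario's termination rule to a record-so-far: stabilizing
#' scenarios finish once the sensed MAP has first reached the target
#' fraction (99% by default) and the stabilization time (15 min) has since
#' elapsed, with a hard safety cap; time-capped scenarios finish at the cap
#' regardless of whether the target was reached.
#'
#' @param spec A [scenario_spec()].
#' @param record Data frame with columns `time_s` and `sensed_map_mmHg`
#'   (times relative to scenario start).
#' @param target Target MAP, mmHg.
#' @param hard_cap_min Safety cap for stabilizing scenarios, minutes.
#' @return `"continue"` or `"done"`.
#' @export
check_termination <- function(spec, record, target = 68, hard_cap_min = 60) {
  stopifnot(nrow(record) > 0)
  t_now <- record$time_s[nrow(record)]
  if (spec$termination$type == "time_cap") {
    if (t_now >= spec$termination$time_cap_min * 60) return("done")
    return("continue")
  }
  if (t_now >= hard_cap_min * 60) return("done")
  thr <- spec$termination$target_fraction * target
  hit <- which(record$sensed_map_mmHg >= thr)
  if (length(hit) > 0 &&
      t_now >= record$time_s[hit[1]] + spec$termination$stabilize_min * 60) {
    return("done")
  }
  "continue"
}

# resolve a scenario's initial HF against the outflow config
resolve_hf_init <- function(spec, cfg) {
  if (is.numeric(spec$hf_init)) return(spec$hf_init)
  switch(spec$hf_init,
         high = cfg$hf_init_high,
         low = cfg$hf_init_low,
         stop(sprintf("unknown hf_init '%s'", spec$hf_init), call. = FALSE))
}

#' Run one scenario
#'
#' Advances the coupled loop: the plant volume integrates at `dt` (0.1 s),
#' the outflow engine and record update at 1 s cadence, and the controller
#' updates at its own sampling period with a zero-order hold. The sensed
#' MAP is the trailing 5 s window average of the synthesized waveform.
#'
#' @param spec A [scenario_spec()].
#' @param ctrl A [controller_config()].
#' @param plant A [plant_state()] (as returned by [initialize_run()] or a
#'   previous scenario).
#' @param cfg An [outflow_config()].
#' @param wf A [waveform_config()].
#' @param noise Apply multiplicative hemorrhage noise (drawn from the
#'   session RNG)?
#' @param dt Plant integration step, s.
#' @param hard_cap_min Safety cap for stabilizing scenarios, minutes.
#' @return The run record: a data frame at 1 s cadence with pressure, flow,
#'   hemorrhage-factor and bookkeeping columns. Attributes: `info` (target
#'   reach/termination summary), `final_plant`, `final_hem`.
#' @export
run_scenario <- function(spec, ctrl, plant, cfg = outflow_config(),
                         wf = waveform_config(), noise = TRUE, dt = 0.1,
                         hard_cap_min = 60) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(ctrl, "controller_config"),
            inherits(plant, "plant_state"))
  target <- ctrl$table$target
  profile <- plant$profile
  if (profile$infusate != spec$infusate) {
    stop(sprintf("active vessel is %s but scenario %d requires %s",
                 profile$infusate, spec$id, spec$infusate), call. = FALSE)
  }
  coag_rate <- if (spec$infusate == "whole_blood") cfg$coag_rate_wb
               else cfg$coag_rate_crystalloid
  hf0 <- resolve_hf_init(spec, cfg)
  hem <- hemorrhage_state(hf0, coag_rate = coag_rate,
                          coag_enabled = spec$coag_enabled,
                          hf_cap = spec$hf_cap,
                          event_ramp_rate = spec$hf_ramp_rate)
  if (spec$open_with_rebleed) {
    hem <- apply_event(hem, "massive_hemorrhage", cfg)
  }

  # fast local copies for the inner loop
  gz <- profile$grid_z; gv <- profile$grid_vol
  scale2 <- profile$variability_scale^2
  hydro <- profile$hydro_constant
  cap <- vessel_capacity(profile)
  offset <- plant$pressure_offset
  vaso_step <- plant$vasopressor_step
  vaso_on <- plant$vasopressor_on
  amp2 <- wf$pulse_amplitude / 2
  omega <- 2 * pi * wf$pulse_rate / 60
  base_p <- function(v) {
    vm <- v * 1000 / scale2
    i <- findInterval(vm, gv, all.inside = TRUE)
    z <- gz[i] + (gz[i + 1L] - gz[i]) * (vm - gv[i]) / (gv[i + 1L] - gv[i])
    z / hydro + offset + if (vaso_on) vaso_step else 0
  }

  t0 <- plant$time
  volume <- plant$volume
  n_sub <- round(1 / dt)
  n_buf <- n_sub * 5L + 1L  # 5 s trailing window
  # seed the window with the pre-scenario steady history
  buf <- base_p(volume) + amp2 * cos(omega * (t0 - (n_buf - 1):0 * dt))
  # trapezoid weights for the uniform window
  w <- c(0.5, rep(1, n_buf - 2L), 0.5) / (n_buf - 1L)

  max_s <- if (spec$termination$type == "time_cap") {
    spec$termination$time_cap_min * 60
  } else hard_cap_min * 60
  nr <- max_s + 1L
  rec <- list(time_s = numeric(nr), sensed_map_mmHg = numeric(nr),
              q_infusion_mL_min = numeric(nr),
              q_hemorrhage_mL_min = numeric(nr),
              q_urine_mL_min = numeric(nr), hf = numeric(nr),
              event_active = character(nr), vasopressor_on = logical(nr),
              cum_infused_mL = numeric(nr), cum_outflow_mL = numeric(nr))
  held <- 0; cum_in <- 0; cum_out <- 0
  reach_t <- NA_real_; release_t <- NA_real_
  # target attainment is judged on the resuscitation phase, i.e. once any
  # opening re-bleed has released
  resuscitating <- !spec$open_with_rebleed
  vaso_off_t <- NA_real_; vaso_on_t <- NA_real_
  starved <- FALSE; overflowed <- FALSE
  stab_s <- if (spec$termination$type == "stabilize") {
    spec$termination$stabilize_min * 60
  } else Inf
  # time-capped scenarios still report whether the target fraction was hit
  thr <- spec$termination$target_fraction %||% 0.99
  # vasopressor without an opening re-bleed engages at scenario start
  if (!is.null(spec$vasopressor) && !spec$open_with_rebleed) {
    vaso_on <- TRUE; vaso_on_t <- 0
    vaso_off_t <- spec$vasopressor$duration_min * 60
  }

  k <- 0L
  repeat {
    t_rel <- as.numeric(k)
    sensed <- sum(w * buf)
    # massive-hemorrhage release once the pressure has bled down (or the
    # event has run its maximum course against a counteracting controller)
    if (!is.null(hem$event) && hem$event == "massive_hemorrhage" &&
        (sensed <= spec$rebleed_release_map ||
         t_rel >= spec$rebleed_max_min * 60)) {
      hem <- release_event(hem)
      release_t <- t_rel
      resuscitating <- TRUE
      if (spec$after_release == "ramp_to_cap") {
        hem <- apply_event(hem, "ramp_to_cap", cfg, hf_cap = spec$hf_cap)
      }
      if (!is.null(spec$vasopressor)) {
        vaso_on <- TRUE; vaso_on_t <- t_rel
        vaso_off_t <- t_rel + spec$vasopressor$duration_min * 60
      }
    }
    if (vaso_on && !is.na(vaso_off_t) && t_rel >= vaso_off_t) {
      vaso_on <- FALSE
    }
    q_h <- hemorrhage_rate(hem, sensed, cfg, noise = noise)
    q_u <- urine_rate(sensed, cfg)
    if (q_h + q_u > cfg$pump_clamp[2]) q_h <- cfg$pump_clamp[2] - q_u
    # the opening re-bleed re-initializes the scenario to its starting
    # pressure; infusion is suspended until it releases (the controller
    # then resumes at its next sampling instant)
    if (!is.null(hem$event) && hem$event == "massive_hemorrhage") {
      held <- 0
    } else {
      held <- controller_update(ctrl, t_rel, sensed, held)
    }

    i <- k + 1L
    rec$time_s[i] <- t_rel
    rec$sensed_map_mmHg[i] <- sensed
    rec$q_infusion_mL_min[i] <- held
    rec$q_hemorrhage_mL_min[i] <- q_h
    rec$q_urine_mL_min[i] <- q_u
    rec$hf[i] <- hf_effective(hem, cfg)
    rec$event_active[i] <- if (is.null(hem$event)) "" else hem$event
    rec$vasopressor_on[i] <- vaso_on
    rec$cum_infused_mL[i] <- cum_in
    rec$cum_outflow_mL[i] <- cum_out

    if (!is.finite(sensed) || !is.finite(volume)) {
      stop(sprintf("non-finite state at t = %.0f s (scenario %d)",
                   t_rel, spec$id), call. = FALSE)
    }
    if (is.na(reach_t) && resuscitating && sensed >= thr * target) {
      reach_t <- t_rel
    }
    done <- if (spec$termination$type == "time_cap") {
      t_rel >= max_s
    } else {
      (!is.na(reach_t) && t_rel >= reach_t + stab_s) || t_rel >= max_s
    }
    if (done) break

    # hemorrhage factor evolves over the coming second
    hem <- update_hemorrhage_factor(hem, sensed, 1 / 60, cfg)
    dv <- (held - q_h - q_u) * dt / 60
    for (j in seq_len(n_sub)) {
      volume <- volume + dv
      if (volume < 0) { volume <- 0; starved <- TRUE }
      if (volume > cap) { volume <- cap; overflowed <- TRUE }
      tt <- t0 + t_rel + j * dt
      buf <- c(buf[-1L], base_p(volume) + amp2 * cos(omega * tt))
    }
    cum_in <- cum_in + held / 60
    cum_out <- cum_out + (q_h + q_u) / 60
    k <- k + 1L
  }

  n <- k + 1L
  rec <- lapply(rec, function(col) col[seq_len(n)])
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  rec$scenario_id <- spec$id

  out_plant <- plant
  out_plant$volume <- volume
  out_plant$time <- t0 + rec$time_s[n]
  out_plant$vasopressor_on <- vaso_on
  out_plant$starved <- plant$starved || starved
  out_plant$overflowed <- plant$overflowed || overflowed
  if (!is.null(plant$deficit_mL)) {
    out_plant$deficit_mL <- plant$deficit_mL - cum_in + cum_out
  }
  resus <- if (spec$open_with_rebleed && !is.na(release_t)) {
    rec[rec$time_s >= release_t, , drop = FALSE]
  } else rec
  info <- list(
    scenario_id = spec$id,
    duration_s = rec$time_s[n],
    target_reached = !is.na(reach_t),
    reach_time_s = reach_t,
    rebleed_release_time_s = release_t,
    vasopressor_on_s = vaso_on_t, vasopressor_off_s = vaso_off_t,
    capped = is.na(reach_t) && spec$termination$type == "stabilize",
    overpressure_events = count_overpressure(resus$sensed_map_mmHg,
                                             cfg$overpressure_threshold),
    starved = starved, overflowed = overflowed,
    hf_final = hem$hf)
  attr(rec, "info") <- info
  attr(rec, "final_plant") <- out_plant
  attr(rec, "final_hem") <- hem
  attr(rec, "target") <- target
  rec
}

# number of distinct excursions above the over-pressure threshold
count_overpressure <- function(map, threshold) {
  above <- map > threshold
  sum(diff(c(FALSE, above)) == 1)
}

#' Run the four chained scenarios
#'
#' Scenarios run in succession with state carried over: the plant volume,
#' clock and deficit ledger persist, scenarios 2 and 3 open with the
#' massive-hemorrhage event, scenario 3 applies the vasopressor bolus
#' immediately after its re-bleed releases, and the vessel is switched to
#' crystalloid with pressure continuity before scenario 4. Optionally the
#' baseline is re-initialized to the starting MAP between scenarios.
#'
#' @param specs List of [scenario_spec()]s, ordered.
#' @param ctrl A [controller_config()].
#' @param wb_profile,crys_profile Whole-blood and crystalloid
#'   [vessel_profile()]s.
#' @param cfg An [outflow_config()].
#' @param wf A [waveform_config()].
#' @param seed Integer seed for the hemorrhage noise.
#' @param noise Apply hemorrhage noise?
#' @param reset_baseline Re-initialize to `start_map` between scenarios
#'   instead of carrying pressure over.
#' @param start_map,deficit_mL Initial condition (see [initialize_run()]).
#' @param dt Plant integration step, s.
#' @param hard_cap_min Safety cap per stabilizing scenario, minutes.
#' @return A combined run record (rows of all scenarios, `time_s` relative
#'   to each scenario's start) with attributes `scenario_info` (list of
#'   per-scenario summaries), `target`, and `final_plant`.
#' @export
run_sequence <- function(specs = default_scenarios("low"),
                         ctrl = controller_config(),
                         wb_profile = design_vessel_from_curve(default_wb_curve()),
                         crys_profile = design_vessel_from_curve(default_crystalloid_curve()),
                         cfg = outflow_config(), wf = waveform_config(),
                         seed = 0, noise = TRUE, reset_baseline = FALSE,
                         start_map = 40, deficit_mL = 2300, dt = 0.1,
                         hard_cap_min = 60) {
  set.seed(seed)
  plant <- initialize_run(wb_profile, start_map = start_map,
                          deficit_mL = deficit_mL)
  records <- vector("list", length(specs))
  infos <- vector("list", length(specs))
  switch_log <- list()
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    if (spec$infusate != plant$profile$infusate) {
      to <- if (spec$infusate == "crystalloid") crys_profile else wb_profile
      p_before <- plant_base_pressure(plant)
      plant <- switch_infusate(plant, to)
      switch_log[[length(switch_log) + 1L]] <- list(
        before_scenario = spec$id, time_s = plant$time,
        pressure_mmHg = p_before,
        reservoir_fill_mL = plant$reservoir_fill_mL)
    }
    if (reset_baseline && s > 1) {
      plant$volume <- volume_at_pressure(plant$profile,
                                         start_map - plant$pressure_offset)
    }
    rec <- run_scenario(spec, ctrl, plant, cfg = cfg, wf = wf,
                        noise = noise, dt = dt, hard_cap_min = hard_cap_min)
    infos[[s]] <- attr(rec, "info")
    plant <- attr(rec, "final_plant")
    records[[s]] <- rec
  }
  out <- do.call(rbind, lapply(records, function(r) {
    attr(r, "info") <- NULL
    attr(r, "final_plant") <- NULL
    attr(r, "final_hem") <- NULL
    attr(r, "target") <- NULL
    r
  }))
  attr(out, "scenario_info") <- infos
  attr(out, "switch_log") <- switch_log
  attr(out, "target") <- ctrl$table$target
  attr(out, "final_plant") <- plant
  attr(out, "seed") <- seed
  out
}
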