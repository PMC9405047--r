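#' Outflow engine configuration
#'
#' Thresholds and rates governing the automated hemorrhage and urine
#' outflow. Hemorrhage is the product of MAP and the hemorrhage factor (HF,
#' mL/min per mmHg), perturbed by multiplicative uniform noise. Below
#' `map_zero_threshold` bleeding is assumed negligible and HF is treated as
#' zero; above `overpressure_threshold` HF escalates (clots dislodging);
#' `overpressure_reset_margin` above the threshold additionally resets the
#' clotting timer. Urine runs at a fixed basal rate once MAP reaches
#' `urine_threshold`.
#'
#' @param map_zero_threshold MAP (mmHg) below which hemorrhage stops.
#' @param urine_threshold MAP (mmHg) at or above which urine flows.
#' @param urine_rate Basal urine rate, mL/min.
#' @param overpressure_threshold MAP (mmHg) above which HF escalates.
#' @param overpressure_reset_margin mmHg above the threshold at which the
#'   clotting timer is reset.
#' @param noise_fraction Half-width of the uniform multiplicative noise.
#' @param pump_clamp Two-element range (mL/min) for total outflow.
#' @param hf_init_high,hf_init_low Initial HF for the high / low severity
#'   scenarios: 120 and 60 mL/min at a MAP of 68 mmHg.
#' @param hf_event HF imposed by the massive-hemorrhage event: 255 mL/min
#'   at 68 mmHg.
#' @param coag_rate_wb,coag_rate_crystalloid Coagulation decay constants,
#'   per minute, by infusate.
#' @param ramp_rate HF escalation rate above the over-pressure threshold,
#'   (mL/min/mmHg) per minute.
#' @export
outflow_config <- function(map_zero_threshold = 30, urine_threshold = 50,
                           urine_rate = 5, overpressure_threshold = 70,
                           overpressure_reset_margin = 2,
                           noise_fraction = 0.05, pump_clamp = c(0, 600),
                           hf_init_high = 120 / 68, hf_init_low = 60 / 68,
                           hf_event = 255 / 68, coag_rate_wb = 0.05,
                           coag_rate_crystalloid = 0.02, ramp_rate = 0.05) {
  stopifnot(map_zero_threshold < urine_threshold,
            urine_threshold < overpressure_threshold,
            noise_fraction >= 0, noise_fraction < 1,
            length(pump_clamp) == 2L, pump_clamp[1] >= 0,
            pump_clamp[2] > pump_clamp[1],
            hf_init_high > 0, hf_init_low > 0, hf_event > 0,
            coag_rate_wb >= 0, coag_rate_crystalloid >= 0, ramp_rate >= 0)
  structure(list(
    map_zero_threshold = map_zero_threshold,
    urine_threshold = urine_threshold, urine_rate = urine_rate,
    overpressure_threshold = overpressure_threshold,
    overpressure_reset_margin = overpressure_reset_margin,
    noise_fraction = noise_fraction, pump_clamp = pump_clamp,
    hf_init_high = hf_init_high, hf_init_low = hf_init_low,
    hf_event = hf_event, coag_rate_wb = coag_rate_wb,
    coag_rate_crystalloid = coag_rate_crystalloid,
    ramp_rate = ramp_rate), class = "outflow_config")
}

#' Hemorrhage state
#'
#' Mutable state of the hemorrhage logic: the current hemorrhage factor,
#' the infusate-dependent coagulation decay constant, whether coagulation
#' is enabled, any active event override, and the clotting timer.
#'
#' @param hf Hemorrhage factor, mL/min per mmHg.
#' @param coag_rate Exponential decay constant, per minute.
#' @param coag_enabled Logical; the fourth test scenario disables clotting.
#' @param hf_cap Upper bound on HF during a `ramp_to_cap` event.
#' @param event_ramp_rate Growth rate of HF during a `ramp_to_cap` event,
#'   (mL/min/mmHg) per minute; `NA` falls back to the outflow config's
#'   over-pressure escalation rate.
#' @export
hemorrhage_state <- function(hf, coag_rate = 0.05, coag_enabled = TRUE,
                             hf_cap = NA_real_,
                             event_ramp_rate = NA_real_) {
  stopifnot(hf >= 0, coag_rate >= 0)
  structure(list(hf = hf, coag_rate = coag_rate,
                 coag_enabled = isTRUE(coag_enabled),
                 event = NULL, hf_cap = hf_cap,
                 event_ramp_rate = event_ramp_rate,
                 time_since_clot_reset = 0),
            class = "hemorrhage_state")
}

# effective HF given any active event
hf_effective <- function(state, cfg) {
  if (!is.null(state$event) && state$event == "massive_hemorrhage") {
    cfg$hf_event
  } else {
    state$hf
  }
}

#' Hemorrhage outflow rate
#'
#' `MAP * HF`, zeroed below the low-MAP shutoff, perturbed by uniform
#' multiplicative noise when `noise = TRUE`, and clamped to the outflow
#' pump's range. One noise draw is consumed per call.
#'
#' @param state A [hemorrhage_state()].
#' @param map Sensed MAP, mmHg.
#' @param cfg An [outflow_config()].
#' @param noise Draw multiplicative noise from the session RNG? (`FALSE`
#'   gives the noise-free rate.)
#' @return Rate in mL/min.
#' @export
hemorrhage_rate <- function(state, map, cfg = outflow_config(),
                            noise = FALSE) {
  stopifnot(map >= 0)
  hf <- hf_effective(state, cfg)
  if (map < cfg$map_zero_threshold) return(0)
  u <- if (isTRUE(noise)) {
    stats::runif(1, -cfg$noise_fraction, cfg$noise_fraction)
  } else 0
  min(max(map * hf * (1 + u), cfg$pump_clamp[1]), cfg$pump_clamp[2])
}

#' Basal urine output rate
#'
#' Fixed basal rate at or above the urine threshold (inclusive at
#' 50 mmHg), zero below it.
#'
#' @inheritParams hemorrhage_rate
#' @export
urine_rate <- function(map, cfg = outflow_config()) {
  stopifnot(map >= 0)
  if (map >= cfg$urine_threshold) cfg$urine_rate else 0
}

#' Advance the hemorrhage factor by one time step
#'
#' In the neutral MAP band (above the shutoff, at or below the
#' over-pressure threshold) and with coagulation enabled, HF decays
#' exponentially at the coagulation rate. Above the over-pressure threshold
#' HF grows linearly at the escalation rate (dislodged clots re-bleeding),
#' and more than `overpressure_reset_margin` above it the clotting timer is
#' reset. An active `massive_hemorrhage` event bypasses both; a
#' `ramp_to_cap` event grows HF monotonically to `hf_cap` with coagulation
#' suppressed.
#'
#' @param state A [hemorrhage_state()].
#' @param map Sensed MAP, mmHg.
#' @param dt Step, minutes.
#' @param cfg An [outflow_config()].
#' @export
update_hemorrhage_factor <- function(state, map, dt, cfg = outflow_config()) {
  stopifnot(dt > 0)
  if (!is.null(state$event)) {
    if (state$event == "massive_hemorrhage") {
      return(state) # scripted override: decay and escalation suspended
    }
    if (state$event == "ramp_to_cap") {
      r <- if (is.na(state$event_ramp_rate)) cfg$ramp_rate
           else state$event_ramp_rate
      state$hf <- min(state$hf + r * dt, state$hf_cap)
      return(state)
    }
  }
  if (map > cfg$overpressure_threshold) {
    state$hf <- state$hf + cfg$ramp_rate * dt
    if (map > cfg$overpressure_threshold + cfg$overpressure_reset_margin) {
      state$time_since_clot_reset <- 0
    } else {
      state$time_since_clot_reset <- state$time_since_clot_reset + dt
    }
  } else if (map > cfg$map_zero_threshold) {
    if (state$coag_enabled) {
      state$hf <- state$hf * exp(-state$coag_rate * dt)
    }
    state$time_since_clot_reset <- state$time_since_clot_reset + dt
  } else {
    state$time_since_clot_reset <- state$time_since_clot_reset + dt
  }
  state
}

#' Apply a scripted hemorrhage event
#'
#' `massive_hemorrhage` immediately imposes the event hemorrhage factor
#' (255 mL/min at a MAP of 68 mmHg by default), emulating a tourniquet
#' suddenly coming loose; it persists until released with
#' [release_event()]. `ramp_to_cap` switches HF into monotone growth toward
#' `hf_cap` with coagulation suppressed, emulating a non-clotting
#' (coagulopathic) hemorrhage.
#'
#' @param state A [hemorrhage_state()].
#' @param event `"massive_hemorrhage"` or `"ramp_to_cap"`.
#' @param cfg An [outflow_config()].
#' @param hf_cap Required for `ramp_to_cap`: the user-defined HF limit.
#' @export
apply_event <- function(state, event, cfg = outflow_config(),
                        hf_cap = NULL) {
  if (!event %in% c("massive_hemorrhage", "ramp_to_cap")) {
    stop(sprintf("unknown event '%s'", event), call. = FALSE)
  }
  if (!is.null(state$event) && state$event == event) {
    stop(sprintf("event '%s' is already active", event), call. = FALSE)
  }
  if (event == "ramp_to_cap") {
    cap <- if (!is.null(hf_cap)) hf_cap else state$hf_cap
    if (is.null(cap) || is.na(cap)) {
      stop("ramp_to_cap requires an explicit hf_cap", call. = FALSE)
    }
    state$hf_cap <- cap
    state$coag_enabled <- FALSE
  }
  state$event <- event
  state
}

#' Release the active event
#'
#' Restores the scripted hemorrhage factor and restarts the clotting timer.
#'
#' @param state A [hemorrhage_state()].
#' @export
release_event <- function(state) {
  state["event"] <- list(NULL)  # keep the slot; $<- NULL would drop it
  state$time_since_clot_reset <- 0
  state
}
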