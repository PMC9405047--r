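#' Pulsatile waveform configuration
#'
#' The circulating pump imposes a pulsatile component on the sensed arterial
#' pressure. The pulse is modelled as a pure cosine at the pulse rate,
#' scaled to the requested peak-to-trough amplitude. A cosine is exactly
#' zero-mean over whole beats under both continuous integration and uniform
#' sampling, so the windowed MAP is independent of the pulse.
#'
#' @param stroke_volume Stroke volume, mL (bookkeeping only; the loop
#'   recirculates, so stroke volume does not change contained volume).
#' @param pulse_rate Beats per minute.
#' @param pulse_amplitude Peak-to-trough amplitude, mmHg.
#' @param sample_rate Waveform synthesis rate, Hz; must satisfy Nyquist for
#'   the pulse frequency.
#' @export
waveform_config <- function(stroke_volume = 2, pulse_rate = 120,
                            pulse_amplitude = 10, sample_rate = 100) {
  stopifnot(pulse_rate > 0, pulse_amplitude >= 0, stroke_volume > 0)
  if (sample_rate < 2 * pulse_rate / 60) {
    stop("sample_rate must be at least twice the pulse frequency",
         call. = FALSE)
  }
  structure(list(stroke_volume = stroke_volume, pulse_rate = pulse_rate,
                 pulse_amplitude = pulse_amplitude,
                 sample_rate = sample_rate),
            class = "waveform_config")
}

#' Plant state
#'
#' Instantaneous state of the simulated circulatory loop: the active vessel,
#' its contained volume, the vasopressor resistance flag, and the clock.
#' `pressure_offset` models the static elevation of the loop's pressure
#' tap relative to the vessel port; `vasopressor_step` is the additive MAP
#' increase produced when the resistance branch is engaged.
#'
#' @param profile Active [vessel_profile()].
#' @param volume Contained volume, mL.
#' @param time Clock, s.
#' @param pressure_offset Static offset, mmHg.
#' @param vasopressor_on Logical.
#' @param vasopressor_step Additive step when engaged, mmHg (default 15).
#' @export
plant_state <- function(profile, volume = 0, time = 0, pressure_offset = 0,
                        vasopressor_on = FALSE, vasopressor_step = 15) {
  stopifnot(inherits(profile, "vessel_profile"),
            volume >= 0, volume <= vessel_capacity(profile) + 1e-9)
  structure(list(profile = profile, volume = volume, time = time,
                 pressure_offset = pressure_offset,
                 vasopressor_on = isTRUE(vasopressor_on),
                 vasopressor_step = vasopressor_step,
                 starved = FALSE, overflowed = FALSE),
            class = "plant_state")
}

#' @export
print.plant_state <- function(x, ...) {
  cat(sprintf(
    "<plant_state> t = %.1f s, %s vessel, %.1f mL, base pressure %.2f mmHg%s\n",
    x$time, x$profile$infusate, x$volume, plant_base_pressure(x),
    if (x$vasopressor_on) " [vasopressor on]" else ""))
  invisible(x)
}

#' Non-pulsatile plant pressure (mmHg)
#'
#' Hydrostatic pressure at the current contained volume plus the static
#' offset and, when engaged, the vasopressor step.
#'
#' @param state A `plant_state`.
#' @export
plant_base_pressure <- function(state) {
  pressure_at_volume(state$profile, state$volume) + state$pressure_offset +
    if (state$vasopressor_on) state$vasopressor_step else 0
}

#' Advance contained volume by one Euler step
#'
#' Contained volume changes by `(q_in - q_out) * dt / 60` and is clamped to
#' the physical range `[0, capacity]`; clamping raises a `starved` /
#' `overflowed` flag on the state rather than failing, matching a physical
#' reservoir that simply runs dry or spills.
#'
#' @param state A `plant_state`.
#' @param q_in,q_out Infusion and outflow rates, mL/min (non-negative).
#' @param dt Step, s.
#' @export
step_volume <- function(state, q_in, q_out, dt) {
  stopifnot(dt > 0, q_in >= 0, q_out >= 0)
  v <- state$volume + (q_in - q_out) * dt / 60
  cap <- vessel_capacity(state$profile)
  if (v < 0) {
    state$starved <- TRUE
    v <- 0
  } else if (v > cap) {
    state$overflowed <- TRUE
    v <- cap
  }
  state$volume <- v
  state$time <- state$time + dt
  state
}

#' Instantaneous arterial pressure sample
#'
#' @param state A `plant_state`.
#' @param t Absolute time, s (governs pulse phase).
#' @param wf A [waveform_config()].
#' @export
instantaneous_pressure <- function(state, t, wf) {
  f <- wf$pulse_rate / 60
  plant_base_pressure(state) + wf$pulse_amplitude / 2 * cos(2 * pi * f * t)
}

#' Windowed mean arterial pressure from a raw waveform
#'
#' Time-weighted (trapezoid) average of the raw pressure samples over the
#' trailing `window` seconds, the sensed MAP supplied to controllers and to
#' the outflow logic.
#'
#' @param raw Data frame with columns `time_s` and `pressure_mmHg`, times
#'   strictly increasing.
#' @param window Window length, s (default 5).
#' @export
sensed_map <- function(raw, window = 5) {
  stopifnot(window > 0)
  t <- raw$time_s; p <- raw$pressure_mmHg
  span <- t[length(t)] - t[1]
  if (span < window - 1e-9) {
    stop(sprintf("raw waveform spans %.2f s; %g s required", span, window),
         call. = FALSE)
  }
  t0 <- t[length(t)] - window
  keep <- t >= t0 - 1e-12
  t <- t[keep]; p <- p[keep]
  trapz_mean(t, p)
}

# trapezoid time-average of p over [t[1], t[n]]
trapz_mean <- function(t, p) {
  n <- length(t)
  dt <- diff(t)
  sum((p[-1] + p[-n]) / 2 * dt) / (t[n] - t[1])
}

#' Engage or release the vasopressor resistance branch
#'
#' Takes effect on the next pressure evaluation as an immediate additive
#' step (default 15 mmHg), emulating the raised systemic vascular resistance
#' of a vasopressor bolus.
#'
#' @param state A `plant_state`.
#' @param on Logical.
#' @export
set_vasopressor <- function(state, on) {
  state$vasopressor_on <- isTRUE(on)
  state
}

#' Switch the active vessel (infusate change-over)
#'
#' The incoming vessel is filled from an external reservoir to the volume
#' that reproduces the current port pressure, so the sensed pressure is
#' continuous across the switch. The volume drawn from the reservoir is
#' recorded on the returned state as `reservoir_fill_mL`; the outgoing
#' vessel's contents are returned to the reservoir, never carried over.
#'
#' @param state A `plant_state` whose active profile is `from`.
#' @param to Target [vessel_profile()].
#' @return Updated `plant_state` with attribute-free bookkeeping fields
#'   `reservoir_fill_mL` and `switch_time_s` set.
#' @export
switch_infusate <- function(state, to) {
  stopifnot(inherits(to, "vessel_profile"))
  p_now <- pressure_at_volume(state$profile, state$volume)
  if (p_now > vessel_max_pressure(to) + 1e-9) {
    stop(sprintf(
      "target vessel capacity pressure %.2f mmHg below current %.2f mmHg",
      vessel_max_pressure(to), p_now), call. = FALSE)
  }
  v_new <- volume_at_pressure(to, p_now)
  state$reservoir_fill_mL <- v_new
  state$switch_time_s <- state$time
  state$profile <- to
  state$volume <- v_new
  state
}
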