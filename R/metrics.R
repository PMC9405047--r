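#' MAP time series
#'
#' A light container pairing a sampled mean arterial pressure trace with
#' its controller target, the input to all performance metrics.
#'
#' @param time_s Sample times, s, strictly increasing.
#' @param map_mmHg Sensed MAP at each sample, mmHg.
#' @param target Target MAP, mmHg (> 0).
#' @export
map_series <- function(time_s, map_mmHg, target = 68) {
  stopifnot(length(time_s) == length(map_mmHg), target > 0)
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s),
                 map_mmHg = as.numeric(map_mmHg),
                 target = target),
            class = "map_series")
}

# coerce a run record (or map_series) to a map_series
as_map_series <- function(x, target = NULL) {
  if (inherits(x, "map_series")) return(x)
  if (is.data.frame(x) && all(c("time_s", "sensed_map_mmHg") %in% names(x))) {
    tgt <- if (!is.null(target)) target else attr(x, "target")
    if (is.null(tgt)) tgt <- 68
    return(map_series(x$time_s, x$sensed_map_mmHg, tgt))
  }
  stop("cannot interpret input as a MAP series", call. = FALSE)
}

#' Performance errors
#'
#' The per-sample percentage deviation of the measured pressure from the
#' controller setpoint: `PE_i = (P_i - P_target) / P_target * 100`.
#'
#' @param series A [map_series()] (or run record).
#' @return Numeric vector of performance errors, percent.
#' @export
performance_errors <- function(series) {
  series <- as_map_series(series)
  (series$map_mmHg - series$target) / series$target * 100
}

#' Varvel controller statistics
#'
#' The four summary statistics of the performance-error trace used to rate
#' closed-loop clinical controllers: MDPE (median PE, the controller's
#' bias), MDAPE (median absolute PE, its accuracy), wobble (median absolute
#' deviation of PE about MDPE, intra-run variability), and divergence (the
#' least-squares slope of `|PE|` against time in minutes, scaled by 60 to
#' percent per hour; a positive value means the controller is drifting away
#' from the setpoint).
#'
#' @param series A [map_series()] (or run record).
#' @return List with elements `mdpe`, `mdape`, `wobble` (percent) and
#'   `divergence` (percent per hour; `NA` with fewer than two samples).
#' @export
varvel_summary <- function(series) {
  series <- as_map_series(series)
  pe <- performance_errors(series)
  mdpe <- stats::median(pe)
  out <- list(mdpe = mdpe,
              mdape = stats::median(abs(pe)),
              wobble = stats::median(abs(pe - mdpe)),
              divergence = NA_real_)
  n <- length(pe)
  if (n >= 2) {
    t_min <- series$time_s / 60
    ape <- abs(pe)
    # closed-form least-squares slope, scaled to %/h
    out$divergence <- 60 *
      (sum(ape * t_min) - sum(ape) * sum(t_min) / n) /
      (sum(t_min^2) - sum(t_min)^2 / n)
  }
  out
}

#' Steady-state detection
#'
#' The steady-state pressure estimate is the mean of the final fraction of
#' the trace (10% by default); the onset is the earliest sample after which
#' every subsequent sample stays within the tolerance band (plus or minus
#' 5% of the estimate). If even the final sample leaves the band the series
#' has no steady state (`found = FALSE`), as happens when the controller
#' diverges from the setpoint.
#'
#' @param series A [map_series()] (or run record).
#' @param band Half-width of the steady band as a fraction of the
#'   steady-state value.
#' @param tail_fraction Fraction of the trace used for the value estimate.
#' @return List with `value` (mmHg), `onset_time` (s) and `found`.
#' @export
detect_steady_state <- function(series, band = 0.05, tail_fraction = 0.1) {
  series <- as_map_series(series)
  p <- series$map_mmHg
  n <- length(p)
  stopifnot(n >= 2)
  n_tail <- max(1L, ceiling(tail_fraction * n))
  value <- mean(p[(n - n_tail + 1L):n])
  dev_ok <- abs(p - value) <= band * abs(value)
  if (!dev_ok[n]) {
    return(list(value = value, onset_time = NA_real_, found = FALSE))
  }
  # earliest index from which the trace stays in band
  last_bad <- if (all(dev_ok)) 0L else max(which(!dev_ok))
  list(value = value, onset_time = series$time_s[last_bad + 1L],
       found = TRUE)
}

#' Step-response metrics
#'
#' Relative overshoot (maximum pressure above the steady-state value, as a
#' percentage of it, floored at zero), effectiveness (percentage of the run
#' duration spent within plus or minus 5 mmHg of the target), and the
#' efficiency rise time (time for the pressure to first reach 90% of the
#' steady-state value).
#'
#' @param series A [map_series()] (or run record).
#' @param ss Result of [detect_steady_state()]; recomputed when missing.
#' @param band_mmHg Half-width of the effectiveness band, mmHg.
#' @return List with `relative_overshoot` (percent), `overshoot_mmHg`,
#'   `effectiveness` (percent) and `efficiency_rise_time` (min); overshoot
#'   and rise time are `NA` when no steady state was found.
#' @export
step_response_metrics <- function(series, ss = NULL, band_mmHg = 5) {
  series <- as_map_series(series)
  if (is.null(ss)) ss <- detect_steady_state(series)
  p <- series$map_mmHg; t <- series$time_s
  n <- length(p)
  # time in band, attributing each inter-sample interval to its left sample
  dt <- diff(t)
  in_band <- abs(p - series$target) <= band_mmHg
  effectiveness <- 100 * sum(dt[in_band[-n]]) / (t[n] - t[1])
  if (!isTRUE(ss$found)) {
    return(list(relative_overshoot = NA_real_, overshoot_mmHg = NA_real_,
                effectiveness = effectiveness,
                efficiency_rise_time = NA_real_))
  }
  over <- max(p) - ss$value
  rise_idx <- which(p >= 0.9 * ss$value)[1]
  rise <- if (is.na(rise_idx)) NA_real_ else (t[rise_idx] - t[1]) / 60
  list(relative_overshoot = max(0, over / ss$value * 100),
       overshoot_mmHg = max(0, over),
       effectiveness = effectiveness,
       efficiency_rise_time = rise)
}

#' Volume metrics
#'
#' Volume efficiency (total volume infused divided by total outflow; values
#' above 1 mean the controller infused more than was lost) and the average
#' commanded infusion rate.
#'
#' @param record A run record (data frame from [run_scenario()] /
#'   [run_sequence()]).
#' @return List with `volume_efficiency` (ratio, `NA` if nothing flowed
#'   out) and `average_infusion_rate` (mL/min).
#' @export
volume_metrics <- function(record) {
  stopifnot(nrow(record) > 0)
  dt_min <- diff(record$time_s) / 60
  q_in <- record$q_infusion_mL_min
  q_out <- record$q_hemorrhage_mL_min + record$q_urine_mL_min
  n <- nrow(record)
  infused <- sum(q_in[-n] * dt_min)
  outflow <- sum(q_out[-n] * dt_min)
  eff <- if (outflow > 0) infused / outflow else {
    warning("zero total outflow; volume efficiency undefined")
    NA_real_
  }
  list(volume_efficiency = eff, average_infusion_rate = mean(q_in))
}

#' Area to setpoint
#'
#' Target-normalized areas between the pressure trace and the setpoint:
#' `sum (P_i - P_target) (t_i - t_{i-1}) / P_target` over samples above
#' (over-resuscitation) and below (under-resuscitation, an oxygen-debt
#' proxy) the target, with time in minutes. Both are reported as
#' non-negative magnitudes in minutes.
#'
#' @param series A [map_series()] (or run record).
#' @return List with `area_above` and `area_below` (min).
#' @export
area_metrics <- function(series) {
  series <- as_map_series(series)
  p <- series$map_mmHg; t <- series$time_s
  stopifnot(length(p) >= 2)
  dt_min <- diff(t) / 60
  dev <- (p[-1] - series$target) / series$target
  contrib <- dt_min * dev
  list(area_above = sum(contrib[dev > 0]),
       area_below = -sum(contrib[dev < 0]))
}

#' Rise area to setpoint
#'
#' The below-target area truncated at the first sample where the pressure
#' reaches 90% of the target: the oxygen-debt burden of the initial
#' resuscitation, reported for the first scenario only in standard reports
#' (later scenarios inherit their starting pressure from the previous one).
#'
#' @param series A [map_series()] (or run record).
#' @return List with `rise_area` (min) and `reached` (logical; when the
#'   trace never reaches 90% of target the full-series area is returned
#'   with `reached = FALSE`).
#' @export
rise_area_to_setpoint <- function(series) {
  series <- as_map_series(series)
  p <- series$map_mmHg
  idx <- which(p >= 0.9 * series$target)[1]
  if (is.na(idx)) {
    return(list(rise_area = area_metrics(series)$area_below,
                reached = FALSE))
  }
  if (idx == 1L) return(list(rise_area = 0, reached = TRUE))
  trunc <- map_series(series$time_s[1:idx], p[1:idx], series$target)
  list(rise_area = area_metrics(trunc)$area_below, reached = TRUE)
}

#' Twelve-metric performance report
#'
#' Computes the full controller performance panel for a run record: the
#' four Varvel statistics, relative overshoot, effectiveness, efficiency
#' rise time, volume efficiency, average infusion rate, the two
#' area-to-setpoint measures, and the rise area to setpoint. Metrics are
#' reported per scenario and across the whole run; wobble is additionally
#' reported restricted to the post-steady-state segment, and the rise area
#' only for the first scenario.
#'
#' @param record A run record from [run_scenario()] or [run_sequence()].
#' @param target Target MAP, mmHg; defaults to the record's own.
#' @return A tidy data frame with columns `scope`, `metric`, `value`,
#'   `units`.
#' @export
performance_report <- function(record, target = NULL) {
  tgt <- if (!is.null(target)) target else attr(record, "target")
  if (is.null(tgt)) tgt <- 68
  scopes <- split(record, record$scenario_id)
  names(scopes) <- paste0("scenario_", names(scopes))
  if (length(scopes) > 1) {
    # whole-run series on a continuous clock
    whole <- record
    whole$time_s <- seq_len(nrow(record)) - 1
    scopes <- c(scopes, list(whole_run = whole))
  }
  rows <- lapply(names(scopes), function(nm) {
    rec <- scopes[[nm]]
    ser <- map_series(rec$time_s, rec$sensed_map_mmHg, tgt)
    vv <- varvel_summary(ser)
    ss <- detect_steady_state(ser)
    sr <- step_response_metrics(ser, ss)
    vm <- volume_metrics(rec)
    am <- area_metrics(ser)
    vals <- c(mdpe = vv$mdpe, mdape = vv$mdape, wobble = vv$wobble,
              divergence = vv$divergence,
              relative_overshoot = sr$relative_overshoot,
              effectiveness = sr$effectiveness,
              efficiency_rise_time = sr$efficiency_rise_time,
              volume_efficiency = vm$volume_efficiency,
              average_infusion_rate = vm$average_infusion_rate,
              area_above = am$area_above, area_below = am$area_below)
    units <- c("%", "%", "%", "%/h", "%", "%", "min", "ratio", "mL/min",
               "min", "min")
    df <- data.frame(scope = nm, metric = names(vals), value = unname(vals),
                     units = units, stringsAsFactors = FALSE)
    # steady-state wobble on the settled segment
    if (isTRUE(ss$found)) {
      post <- rec[rec$time_s >= ss$onset_time, , drop = FALSE]
      if (nrow(post) >= 2) {
        wss <- varvel_summary(map_series(post$time_s, post$sensed_map_mmHg,
                                         tgt))$wobble
        df <- rbind(df, data.frame(scope = nm, metric = "steady_state_wobble",
                                   value = wss, units = "%",
                                   stringsAsFactors = FALSE))
      }
    }
    if (nm == "scenario_1") {
      ra <- rise_area_to_setpoint(ser)
      df <- rbind(df, data.frame(scope = nm, metric = "rise_area",
                                 value = ra$rise_area, units = "min",
                                 stringsAsFactors = FALSE))
    }
    df
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
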