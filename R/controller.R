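#' Six-step decision table
#'
#' A banded mapping from the MAP error (`target - sensed MAP`, mmHg) to a
#' fraction of the maximum infusion rate. Bands are ordered by decreasing
#' lower bound; the first band whose bound does not exceed the error
#' applies, so larger deficits infuse faster and the rate falls off in six
#' logical steps as the target is approached. The last band must map to
#' zero so an at-or-above-target MAP never infuses.
#'
#' @param bands Data frame with columns `lower` (error lower bound, mmHg;
#'   strictly decreasing, last `-Inf`) and `fraction` (of `q_max`;
#'   non-increasing, within `[0, 1]`, last 0). Default shipped table:
#'   error >= 25 -> 1.00, >= 15 -> 0.60, >= 10 -> 0.40, >= 5 -> 0.30,
#'   >= 0.5 -> 0.25, otherwise 0. The lowest non-zero step reaches within
#'   0.5 mmHg of the target so the controller can settle inside 99% of the
#'   setpoint rather than parking at the edge of a wider dead band.
#' @param q_max Maximum infusion rate, mL/min.
#' @param target Target MAP, mmHg.
#' @export
decision_table <- function(bands = default_decision_bands(), q_max = 500,
                           target = 68) {
  stopifnot(q_max > 0, target > 0)
  validate_table(structure(list(bands = bands, q_max = q_max,
                                target = target),
                           class = "decision_table"))
}

#' @rdname decision_table
#' @export
default_decision_bands <- function() {
  data.frame(lower = c(25, 15, 10, 5, 0.5, -Inf),
             fraction = c(1, 0.6, 0.4, 0.3, 0.25, 0))
}

#' Validate a decision table
#'
#' Enforces the six-band structure: exactly six bands, strictly decreasing
#' lower bounds, non-increasing fractions within `[0, 1]`, and a final
#' zero-rate band. Bands are normalized to decreasing-bound order.
#'
#' @param table A `decision_table`.
#' @return The validated table (invisibly usable as input elsewhere).
#' @export
validate_table <- function(table) {
  b <- table$bands
  if (!is.data.frame(b) || !all(c("lower", "fraction") %in% names(b))) {
    stop("bands must be a data frame with columns 'lower' and 'fraction'",
         call. = FALSE)
  }
  if (nrow(b) != 6L) {
    stop(sprintf("decision table must have exactly 6 bands, got %d",
                 nrow(b)), call. = FALSE)
  }
  b <- b[order(b$lower, decreasing = TRUE), , drop = FALSE]
  row.names(b) <- NULL
  if (any(diff(b$lower) >= 0)) {
    stop("band lower bounds must be strictly decreasing", call. = FALSE)
  }
  if (any(b$fraction < 0 | b$fraction > 1)) {
    stop("band fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(b$fraction) > 0)) {
    stop("band fractions must be non-increasing toward the target",
         call. = FALSE)
  }
  if (b$fraction[6] != 0) {
    stop("the lowest band must map to fraction 0 (no infusion at target)",
         call. = FALSE)
  }
  table$bands <- b
  table
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("<decision_table> target %g mmHg, Q_max %g mL/min\n",
              x$target, x$q_max))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Decision-table infusion rate
#'
#' @param table A [decision_table()].
#' @param map Sensed MAP, mmHg.
#' @return Infusion rate, mL/min.
#' @export
decision_table_rate <- function(table, map) {
  stopifnot(map >= 0)
  err <- table$target - map
  i <- which(table$bands$lower <= err)[1]
  if (is.na(i)) return(0)
  table$bands$fraction[i] * table$q_max
}

#' Controller configuration
#'
#' @param sampling_period Seconds between decision updates (the reference
#'   configurations are 120 s and 5 s); the output is held constant
#'   (zero-order hold) in between.
#' @param table A [decision_table()].
#' @export
controller_config <- function(sampling_period = 120,
                              table = decision_table()) {
  stopifnot(sampling_period > 0)
  structure(list(sampling_period = sampling_period, table = table),
            class = "controller_config")
}

#' Sampled controller update with zero-order hold
#'
#' Recomputes the infusion rate from the decision table only at integer
#' multiples of the sampling period (first update at t = 0); between
#' updates the previously commanded rate is returned unchanged.
#'
#' @param cfg A [controller_config()].
#' @param t Time since the start of the scenario, s.
#' @param map Sensed MAP, mmHg.
#' @param held_rate Currently commanded rate, mL/min.
#' @export
controller_update <- function(cfg, t, map, held_rate) {
  k <- t / cfg$sampling_period
  if (abs(k - round(k)) < 1e-9) {
    decision_table_rate(cfg$table, map)
  } else {
    held_rate
  }
}
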