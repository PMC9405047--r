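#' Pressure-volume response curves
#'
#' A `pv_curve` describes mean arterial pressure (MAP, mmHg) as a function of
#' infused volume (mL) for one infusate type. Whole-blood responsiveness is
#' linear; crystalloid responsiveness is parabolic with stiffness (dP/dV)
#' decreasing as volume accumulates, reflecting redistribution of crystalloid
#' out of the vasculature.
#'
#' @param form `"linear"` (2 coefficients, `P = a + b*V`) or `"parabolic"`
#'   (3 coefficients, `P = a + b*V + c*V^2`).
#' @param coefficients Numeric vector of polynomial coefficients in
#'   increasing order (intercept first). Units: mmHg, mmHg/mL, mmHg/mL^2.
#' @param valid_range Pressure range `c(P_min, P_max)` in mmHg over which
#'   the curve is used; MAP must be strictly increasing in volume there.
#' @return A `pv_curve` object.
#' @export
pv_curve <- function(form = c("linear", "parabolic"), coefficients,
                     valid_range = c(0, 100)) {
  form <- match.arg(form)
  coefficients <- as.numeric(coefficients)
  n_expect <- if (form == "linear") 2L else 3L
  if (length(coefficients) != n_expect) {
    stop(sprintf("form '%s' requires exactly %d coefficients, got %d",
                 form, n_expect, length(coefficients)), call. = FALSE)
  }
  if (length(valid_range) != 2L || valid_range[1] < 0 ||
      valid_range[2] <= valid_range[1]) {
    stop("valid_range must be c(P_min, P_max) with 0 <= P_min < P_max",
         call. = FALSE)
  }
  if (coefficients[2] <= 0 && (form == "linear" || coefficients[3] <= 0)) {
    stop("curve is not strictly increasing: dP/dV <= 0 at V = 0 mL",
         call. = FALSE)
  }
  curve <- structure(
    list(form = form, coefficients = coefficients,
         valid_range = as.numeric(valid_range)),
    class = "pv_curve")
  # monotonicity over the volume interval spanned by the pressure range
  v_lo <- curve_volume(curve, valid_range[1])
  v_hi <- tryCatch(curve_volume(curve, valid_range[2]), error = function(e) {
    stop(sprintf(
      "curve is not strictly increasing up to P_max: it peaks at %.2f mmHg",
      coefficients[1] + coefficients[2]^2 / (4 * abs(coefficients[3]))),
      call. = FALSE)
  })
  vv <- seq(v_lo, v_hi, length.out = 512L)
  slope <- curve_slope(curve, vv)
  if (any(slope <= 0)) {
    bad <- vv[which(slope <= 0)[1]]
    stop(sprintf(
      "curve is not strictly increasing: dP/dV <= 0 at V = %.3f mL", bad),
      call. = FALSE)
  }
  curve
}

#' @export
print.pv_curve <- function(x, ...) {
  cat(sprintf("<pv_curve> %s, MAP valid on [%g, %g] mmHg\n",
              x$form, x$valid_range[1], x$valid_range[2]))
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  invisible(x)
}

# P(V) in mmHg for volume in mL
curve_pressure <- function(curve, volume) {
  co <- curve$coefficients
  if (curve$form == "linear") co[1] + co[2] * volume
  else co[1] + co[2] * volume + co[3] * volume^2
}

# dP/dV in mmHg/mL
curve_slope <- function(curve, volume) {
  co <- curve$coefficients
  if (curve$form == "linear") rep(co[2], length(volume))
  else co[2] + 2 * co[3] * volume
}

# V(P) in mL: analytic inverse on the increasing branch
curve_volume <- function(curve, pressure) {
  co <- curve$coefficients
  if (curve$form == "linear") {
    (pressure - co[1]) / co[2]
  } else {
    disc <- co[2]^2 - 4 * co[3] * (co[1] - pressure)
    if (any(disc < 0)) {
      stop("pressure outside the range attainable by the parabolic curve",
           call. = FALSE)
    }
    (-co[2] + sqrt(disc)) / (2 * co[3])
  }
}

#' Default infusate response curves
#'
#' The whole-blood curve is linear with slope chosen so that the designed
#' vessel is a right cylinder of equivalent radius 27 mm (the slope is then
#' `1 / (pi * 27^2 * 13.595 / 1000)` = 0.03212 mmHg/mL, i.e. 31.14 mL per
#' mmHg). The crystalloid curve is parabolic, `P = 0.034 V - 2.4e-6 V^2`,
#' reaching the 68 mmHg resuscitation target near 2410 mL with stiffness
#' decreasing in volume; both are configuration defaults, not fits to any
#' deposited dataset.
#'
#' @param hydro_constant Hydrostatic conversion, mm of water column per mmHg.
#' @return A `pv_curve`.
#' @export
default_wb_curve <- function(hydro_constant = 13.595) {
  slope <- 1 / (pi * 27^2 * hydro_constant / 1000)
  pv_curve("linear", c(0, slope), valid_range = c(0, 100))
}

#' @rdname default_wb_curve
#' @export
default_crystalloid_curve <- function() {
  pv_curve("parabolic", c(0, 0.034, -2.4e-6), valid_range = c(0, 90))
}

#' Vessel profile: hydrostatic reservoir geometry
#'
#' A vessel profile encodes the radius `r(z)` (mm) of a hydrostatic reservoir
#' at height `z` (mm) above its port. Because the pressure at the port is the
#' height of the water column divided by `hydro_constant`, the contained
#' volume as a function of port pressure is the vessel's pressure-volume
#' relationship. Contained volume is evaluated by composite-trapezoid
#' quadrature of `pi * r(z)^2` on a fixed 0.1 mm height grid; the profile's
#' P-V map is defined as linear interpolation of that cumulative sum, which
#' makes volume/pressure lookups exact inverses of each other.
#'
#' @param r_fun Vectorized function of height z (mm) returning radius (mm).
#' @param height_max Vessel height (mm).
#' @param infusate `"whole_blood"` or `"crystalloid"`.
#' @param variability_scale Dimensionless multiplier on the equivalent
#'   radius used to emulate subject variability; cross-sectional area (and
#'   hence volume at every pressure) scales with its square.
#' @param hydro_constant mm of water column per mmHg (13.595 for water).
#' @param dz Quadrature step in mm.
#' @return A `vessel_profile` object.
#' @export
vessel_profile <- function(r_fun, height_max,
                           infusate = c("whole_blood", "crystalloid"),
                           variability_scale = 1, hydro_constant = 13.595,
                           dz = 0.1) {
  infusate <- match.arg(infusate)
  stopifnot(is.function(r_fun), height_max > 0, hydro_constant > 0,
            variability_scale > 0, dz > 0)
  z <- seq(0, height_max, by = dz)
  if (z[length(z)] < height_max) z <- c(z, height_max)
  r <- r_fun(z)
  if (any(!is.finite(r)) || any(r <= 0)) {
    bad <- z[which(!is.finite(r) | r <= 0)[1]]
    stop(sprintf("radius must be positive and finite; violated at z = %.2f mm",
                 bad), call. = FALSE)
  }
  a <- pi * r^2                               # mm^2
  cumvol <- c(0, cumsum((a[-1] + a[-length(a)]) / 2 * diff(z)))  # mm^3
  structure(
    list(r_fun = r_fun, height_max = height_max, infusate = infusate,
         variability_scale = variability_scale,
         hydro_constant = hydro_constant,
         grid_z = z, grid_vol = cumvol),
    class = "vessel_profile")
}

#' @export
print.vessel_profile <- function(x, ...) {
  cat(sprintf(
    "<vessel_profile> %s, height %.1f mm (%.1f mmHg), capacity %.1f mL\n",
    x$infusate, x$height_max, x$height_max / x$hydro_constant,
    vessel_capacity(x)))
  if (x$variability_scale != 1) {
    cat(sprintf("  subject variability scale: %.3f\n", x$variability_scale))
  }
  invisible(x)
}

#' Vessel capacity in mL
#' @param profile A `vessel_profile`.
#' @export
vessel_capacity <- function(profile) {
  profile$variability_scale^2 *
    profile$grid_vol[length(profile$grid_vol)] / 1000
}

#' Maximum pressure the vessel can supply (mmHg)
#' @param profile A `vessel_profile`.
#' @export
vessel_max_pressure <- function(profile) {
  profile$height_max / profile$hydro_constant
}

# linear interpolation on the height grid; z in mm, returns mm^3 (unscaled)
.vol_at_height <- function(profile, z) {
  i <- findInterval(z, profile$grid_z, all.inside = TRUE)
  z0 <- profile$grid_z[i]; z1 <- profile$grid_z[i + 1L]
  v0 <- profile$grid_vol[i]; v1 <- profile$grid_vol[i + 1L]
  v0 + (v1 - v0) * (z - z0) / (z1 - z0)
}

# inverse interpolation: volume mm^3 (unscaled) -> height mm
.height_at_vol <- function(profile, v) {
  i <- findInterval(v, profile$grid_vol, all.inside = TRUE)
  z0 <- profile$grid_z[i]; z1 <- profile$grid_z[i + 1L]
  v0 <- profile$grid_vol[i]; v1 <- profile$grid_vol[i + 1L]
  z0 + (z1 - z0) * (v - v0) / (v1 - v0)
}

#' Contained volume at a port pressure
#'
#' @param profile A `vessel_profile`.
#' @param pressure Port pressure in mmHg.
#' @return Volume in mL.
#' @export
volume_at_pressure <- function(profile, pressure) {
  p_max <- vessel_max_pressure(profile)
  if (any(pressure < 0)) stop("pressure must be non-negative", call. = FALSE)
  if (any(pressure > p_max + 1e-9)) {
    stop(sprintf(
      "pressure %.3f mmHg exceeds vessel capacity pressure %.3f mmHg (%.1f mL)",
      max(pressure), p_max, vessel_capacity(profile)), call. = FALSE)
  }
  z <- pmin(pressure * profile$hydro_constant, profile$height_max)
  profile$variability_scale^2 * .vol_at_height(profile, z) / 1000
}

#' Port pressure at a contained volume
#'
#' Exact inverse of [volume_at_pressure()] on the profile's interpolated
#' pressure-volume map.
#'
#' @param profile A `vessel_profile`.
#' @param volume Contained volume in mL.
#' @return Pressure in mmHg.
#' @export
pressure_at_volume <- function(profile, volume) {
  cap <- vessel_capacity(profile)
  if (any(volume < -1e-9) || any(volume > cap + 1e-9)) {
    stop(sprintf("volume outside [0, %.1f] mL", cap), call. = FALSE)
  }
  v_mm3 <- pmax(0, pmin(volume, cap)) * 1000 / profile$variability_scale^2
  .height_at_vol(profile, v_mm3) / profile$hydro_constant
}

#' Design a vessel from a target pressure-volume curve
#'
#' Inverts the target MAP-vs-volume curve to volume as a function of
#' pressure, substitutes height for pressure through the hydrostatic column
#' relation `z = P * hydro_constant`, and recovers the radius profile from
#' `r(z) = sqrt((1/pi) dV/dz)`. A linear curve yields a right cylinder; a
#' parabolic curve with decreasing stiffness yields a funnel whose radius
#' grows with height.
#'
#' @param curve A [pv_curve()].
#' @param hydro_constant mm of water column per mmHg.
#' @param dz Quadrature step (mm) for the resulting profile.
#' @return A `vessel_profile` whose `infusate` is `"whole_blood"` for linear
#'   curves and `"crystalloid"` for parabolic curves.
#' @export
design_vessel_from_curve <- function(curve, hydro_constant = 13.595,
                                     dz = 0.1) {
  stopifnot(inherits(curve, "pv_curve"), hydro_constant > 0)
  p_max <- curve$valid_range[2]
  # dV/dz <= 0 would mean an unbuildable (non-positive) cross-section
  p_chk <- seq(1e-9, p_max, length.out = 512L)
  slope <- curve_slope(curve, curve_volume(curve, p_chk))
  if (any(slope <= 0)) {
    bad <- p_chk[which(slope <= 0)[1]]
    stop(sprintf("dV/dz <= 0 at P = %.3f mmHg: curve cannot be realised",
                 bad), call. = FALSE)
  }
  r_fun <- function(z) {
    p <- z / hydro_constant
    v <- curve_volume(curve, p)              # mL
    dv_dp <- 1 / curve_slope(curve, v)       # mL / mmHg
    dv_dz <- dv_dp / hydro_constant * 1000   # mm^3 / mm
    sqrt(dv_dz / pi)
  }
  infusate <- if (curve$form == "linear") "whole_blood" else "crystalloid"
  vessel_profile(r_fun, height_max = p_max * hydro_constant,
                 infusate = infusate, hydro_constant = hydro_constant,
                 dz = dz)
}

#' Emulate subject variability
#'
#' Returns a copy of the profile with the equivalent radius multiplied by
#' `scale`; the volume held at every pressure scales by `scale^2`.
#'
#' @param profile A `vessel_profile`.
#' @param scale Positive dimensionless multiplier.
#' @export
apply_subject_variation <- function(profile, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale must be a single positive number", call. = FALSE)
  }
  profile$variability_scale <- profile$variability_scale * scale
  profile
}

#' Constant-rate characterization infusion
#'
#' Reproduces a bench characterization run: fluid is infused at a constant
#' rate starting from the volume corresponding to `p_start`, and the port
#' pressure is recorded against infused volume until `p_end` is reached.
#'
#' @param profile A `vessel_profile`.
#' @param rate Infusion rate, mL/min.
#' @param p_start,p_end Start and end pressures, mmHg.
#' @param dt Sampling interval, s.
#' @return A data frame with columns `time_s`, `infused_volume_mL`,
#'   `pressure_mmHg`.
#' @export
simulate_constant_infusion <- function(profile, rate = 500, p_start = 40,
                                       p_end = 68, dt = 1) {
  stopifnot(rate > 0, dt > 0, p_start <= p_end)
  p_cap <- vessel_max_pressure(profile)
  if (p_end > p_cap) {
    warning(sprintf(
      "p_end %.2f mmHg exceeds capacity pressure %.2f mmHg; trace truncated",
      p_end, p_cap))
    p_end <- p_cap
  }
  if (p_start >= p_end) {
    return(data.frame(time_s = numeric(0), infused_volume_mL = numeric(0),
                      pressure_mmHg = numeric(0)))
  }
  v0 <- volume_at_pressure(profile, p_start)
  v_end <- volume_at_pressure(profile, p_end)
  total <- v_end - v0
  t_end <- total / rate * 60
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  infused <- rate * times / 60
  data.frame(time_s = times, infused_volume_mL = infused,
             pressure_mmHg = pressure_at_volume(profile, v0 + infused))
}
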