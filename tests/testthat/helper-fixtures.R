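# shared fixtures, built once per test run

wb_profile <- design_vessel_from_curve(default_wb_curve())
crys_profile <- design_vessel_from_curve(default_crystalloid_curve())

# slope of the default whole-blood curve, mL per mmHg (27 mm cylinder)
wb_ml_per_mmhg <- pi * 27^2 * 13.595 / 1000

# numerical quadrature oracle for contained volume (mL) at pressure P
quadrature_volume <- function(profile, pressure) {
  z_max <- pressure * profile$hydro_constant
  profile$variability_scale^2 *
    stats::integrate(function(z) pi * profile$r_fun(z)^2, 0, z_max,
                     rel.tol = 1e-10)$value / 1000
}

# a constant-pressure raw waveform data frame
flat_waveform <- function(p, t_end = 6, dt = 0.1) {
  t <- seq(0, t_end, by = dt)
  data.frame(time_s = t, pressure_mmHg = rep(p, length(t)))
}
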