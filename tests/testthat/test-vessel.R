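test_that("a linear MAP-volume curve designs a right cylinder", {
  # slope chosen so V(P) = 31.135 mL/mmHg * P  =>  r = 27 mm at all heights
  prof <- wb_profile
  r <- prof$r_fun(c(0.1, 100, 500, 1000))
  expect_equal(r, rep(27, 4), tolerance = 1e-9)

  # any linear curve gives a height-independent radius
  curve <- pv_curve("linear", c(0, 0.05), valid_range = c(0, 80))
  p2 <- design_vessel_from_curve(curve)
  expect_lt(diff(range(p2$r_fun(c(1, 200, 800)))), 1e-9)
})

test_that("degenerate curves are rejected with the violation located", {
  expect_error(pv_curve("linear", c(0, 0)), "strictly increasing")
  expect_error(pv_curve("linear", c(0, 0.03, 1)), "exactly 2")
  # parabola that flattens inside the requested range
  expect_error(pv_curve("parabolic", c(0, 0.02, -1e-5), valid_range = c(0, 60)),
               "strictly increasing")
})

test_that("volume at pressure matches the hydrostatic column closed form", {
  expect_equal(volume_at_pressure(wb_profile, 10),
               pi * 27^2 * 10 * 13.595 / 1000, tolerance = 1e-9)
  expect_identical(volume_at_pressure(wb_profile, 0), 0)
  # area scales with the square of the equivalent radius
  prof11 <- apply_subject_variation(wb_profile, 1.1)
  expect_equal(volume_at_pressure(prof11, 10),
               1.21 * volume_at_pressure(wb_profile, 10), tolerance = 1e-12)
  expect_error(volume_at_pressure(wb_profile, 150), "exceeds vessel capacity")
})

test_that("cylinder volume equals numerical quadrature", {
  for (p in c(5, 20, 68)) {
    expect_equal(volume_at_pressure(wb_profile, p),
                 quadrature_volume(wb_profile, p), tolerance = 1e-9)
  }
  for (p in c(10, 40, 68)) {
    expect_equal(volume_at_pressure(crys_profile, p),
                 quadrature_volume(crys_profile, p), tolerance = 1e-6)
  }
})

test_that("pressure and volume lookups are mutual inverses", {
  expect_equal(pressure_at_volume(wb_profile,
                                  volume_at_pressure(wb_profile, 10)),
               10, tolerance = 1e-6)
  expect_identical(pressure_at_volume(wb_profile, 0), 0)
  set.seed(11)
  for (prof in list(wb_profile, crys_profile,
                    apply_subject_variation(crys_profile, 0.9))) {
    p <- stats::runif(100, 0, vessel_max_pressure(prof))
    back <- vapply(p, function(pp) {
      pressure_at_volume(prof, volume_at_pressure(prof, pp))
    }, numeric(1))
    expect_lt(max(abs(back - p)), 1e-5)
  }
})

test_that("subject variation scales the pressure-volume slope quadratically", {
  prof <- apply_subject_variation(wb_profile, 0.9)
  expect_equal(volume_at_pressure(prof, 25),
               0.81 * volume_at_pressure(wb_profile, 25), tolerance = 1e-12)
  same <- apply_subject_variation(wb_profile, 1)
  expect_equal(volume_at_pressure(same, 33),
               volume_at_pressure(wb_profile, 33), tolerance = 1e-12)
  expect_error(apply_subject_variation(wb_profile, -1), "positive")
  expect_error(apply_subject_variation(wb_profile, 0), "positive")
})

test_that("constant infusion reproduces the design curve", {
  tr <- simulate_constant_infusion(wb_profile, rate = 500, p_start = 40,
                                   p_end = 68)
  expect_equal(max(tr$infused_volume_mL), 28 * wb_ml_per_mmhg,
               tolerance = 1e-6)
  # linear curve: pressure linear in infused volume
  fit <- stats::lm(pressure_mmHg ~ infused_volume_mL, data = tr)
  expect_lt(max(abs(stats::residuals(fit))), 1e-8)

  # designed vessel reproduces its target curve to better than 0.5 mmHg
  for (curve in list(default_wb_curve(), default_crystalloid_curve())) {
    prof <- design_vessel_from_curve(curve)
    p_end <- curve$valid_range[2]
    tr <- simulate_constant_infusion(prof, 500, 0.5, p_end - 0.5, dt = 0.5)
    v0 <- volume_at_pressure(prof, 0.5)
    co <- curve$coefficients
    v <- v0 + tr$infused_volume_mL
    expected <- if (curve$form == "linear") co[1] + co[2] * v
                else co[1] + co[2] * v + co[3] * v^2
    expect_lt(max(abs(tr$pressure_mmHg - expected)), 0.5)
  }
})

test_that("parabolic vessels show decreasing pressure gain per mL", {
  tr <- simulate_constant_infusion(crys_profile, 500, 5, 85, dt = 1)
  gain <- diff(tr$pressure_mmHg)
  expect_true(all(diff(gain) < 1e-9))  # concave: funnel widens with height
})

test_that("constant infusion handles degenerate and overflowing requests", {
  empty <- simulate_constant_infusion(wb_profile, 500, 50, 50)
  expect_identical(nrow(empty), 0L)
  expect_warning(tr <- simulate_constant_infusion(wb_profile, 500, 90, 150),
                 "truncated")
  expect_lte(max(tr$pressure_mmHg), vessel_max_pressure(wb_profile) + 1e-9)
})

test_that("infusate switch preserves pressure and draws fill from the reservoir", {
  st <- plant_state(wb_profile, volume = volume_at_pressure(wb_profile, 55))
  sw <- switch_infusate(st, crys_profile)
  expect_identical(sw$profile$infusate, "crystalloid")
  expect_equal(pressure_at_volume(sw$profile, sw$volume), 55,
               tolerance = 1e-6)
  # fill volume is accounted against an external reservoir, not conjured
  expect_equal(sw$reservoir_fill_mL,
               volume_at_pressure(crys_profile, 55), tolerance = 1e-9)
  # switching to an identical profile leaves the volume unchanged
  same <- switch_infusate(st, wb_profile)
  expect_equal(same$volume, st$volume, tolerance = 1e-9)
  # a vessel too short for the current pressure is rejected
  low <- design_vessel_from_curve(pv_curve("linear", c(0, 0.05),
                                           valid_range = c(0, 30)))
  expect_error(switch_infusate(st, low), "capacity")
})

test_that("whole-blood then crystalloid infusion is linear then concave", {
  # switch-over run: infuse WB, switch at equal pressure, continue with
  # crystalloid to the 68 mmHg target
  st <- plant_state(wb_profile, volume = volume_at_pressure(wb_profile, 40))
  wb_leg <- simulate_constant_infusion(wb_profile, 500, 40, 55, dt = 1)
  st$volume <- st$volume + max(wb_leg$infused_volume_mL)
  p_mid <- pressure_at_volume(st$profile, st$volume)
  expect_equal(p_mid, 55, tolerance = 1e-6)
  st <- switch_infusate(st, crys_profile)
  crys_leg <- simulate_constant_infusion(crys_profile, 500, p_mid, 68, dt = 1)
  # pressure is continuous across the marked transition
  expect_equal(crys_leg$pressure_mmHg[1],
               wb_leg$pressure_mmHg[nrow(wb_leg)], tolerance = 1e-6)
  # linear before the switch, strictly concave after (the appended final
  # sample breaks the uniform time grid, so it is dropped)
  wb_p <- utils::head(wb_leg$pressure_mmHg, -1)
  crys_p <- utils::head(crys_leg$pressure_mmHg, -1)
  expect_lt(max(abs(diff(diff(wb_p)))), 1e-8)
  expect_true(all(diff(diff(crys_p)) < 1e-9))
})
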