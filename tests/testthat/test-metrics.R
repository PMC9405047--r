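test_that("performance errors are percent deviations from target", {
  ser <- map_series(0:2, c(68, 78, 34), target = 68)
  pe <- performance_errors(ser)
  expect_equal(pe, c(0, 10 / 68 * 100, -50), tolerance = 1e-12)
  expect_error(map_series(0:1, c(60, 60), target = 0), "target > 0")
  expect_error(map_series(c(0, 0), c(60, 60)), "strictly increasing")
})

test_that("Varvel statistics match hand-computed medians", {
  # constant error: pure bias, no wobble, no drift
  ser <- map_series(0:9, rep(68 * 1.03, 10))
  vv <- varvel_summary(ser)
  expect_equal(vv$mdpe, 3, tolerance = 1e-9)
  expect_equal(vv$mdape, 3, tolerance = 1e-9)
  expect_equal(vv$wobble, 0, tolerance = 1e-12)
  expect_equal(vv$divergence, 0, tolerance = 1e-9)

  # PE = {-2, 0, 4}: MDPE 0, MDAPE 2, wobble 2
  p <- 68 * (1 + c(-2, 0, 4) / 100)
  vv <- varvel_summary(map_series(c(0, 60, 120), p))
  expect_equal(vv$mdpe, 0, tolerance = 1e-12)
  expect_equal(vv$mdape, 2, tolerance = 1e-12)
  expect_equal(vv$wobble, 2, tolerance = 1e-12)
})

test_that("divergence is the |PE| slope in percent per hour", {
  # |PE| rising 1 percent per minute over 0..10 min -> 60 %/h
  t_min <- 0:10
  p <- 68 * (1 + t_min / 100)
  ser <- map_series(t_min * 60, p)
  vv <- varvel_summary(ser)
  expect_equal(vv$divergence, 60, tolerance = 1e-9)

  # closed form agrees with an independent least-squares fit
  set.seed(3)
  for (i in 1:5) {
    t_min <- sort(stats::runif(40, 0, 30))
    p <- 68 + stats::rnorm(40, 0, 6)
    ser <- map_series(t_min * 60, p)
    ape <- abs(performance_errors(ser))
    oracle <- 60 * unname(stats::coef(stats::lm(ape ~ t_min))[2])
    expect_equal(varvel_summary(ser)$divergence, oracle,
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under uniform time shift", {
  set.seed(8)
  t <- sort(stats::runif(50, 0, 1800))
  p <- 60 + stats::rnorm(50, 0, 4)
  a <- varvel_summary(map_series(t, p))
  b <- varvel_summary(map_series(t + 600, p))
  expect_equal(a$divergence, b$divergence, tolerance = 1e-9)
  am <- area_metrics(map_series(t, p))
  bm <- area_metrics(map_series(t + 600, p))
  expect_equal(am, bm, tolerance = 1e-12)
})

test_that("MDAPE bounds MDPE and wobble vanishes only for constant error", {
  set.seed(21)
  for (i in 1:20) {
    p <- 68 + stats::rnorm(25, sample(c(-8, 0, 8), 1), stats::runif(1, 0, 6))
    vv <- varvel_summary(map_series(seq_along(p), p))
    expect_gte(vv$mdape, abs(vv$mdpe) - 1e-12)
  }
  expect_gt(varvel_summary(map_series(1:5, c(60, 68, 64, 70, 61)))$wobble, 0)
})

test_that("steady state is detected from the settled tail", {
  # constant series settles immediately
  ss <- detect_steady_state(map_series(0:99, rep(68, 100)))
  expect_true(ss$found)
  expect_equal(ss$value, 68, tolerance = 1e-12)
  expect_identical(ss$onset_time, 0)

  # ramp to target at 10 min, then hold within +/-1: onset near 10 min
  t <- seq(0, 1800, by = 1)
  set.seed(4)
  p <- ifelse(t < 600, 40 + (68 - 40) * t / 600, 68)
  p <- p + ifelse(t >= 600, stats::runif(length(t), -1, 1), 0)
  ss <- detect_steady_state(map_series(t, p))
  expect_true(ss$found)
  expect_equal(ss$value, 68, tolerance = 0.2)
  # in-band from roughly the moment the ramp enters 95% of the tail mean
  expect_gt(ss$onset_time, 480)
  expect_lt(ss$onset_time, 620)

  # strongly diverging series (still moving through the tail window faster
  # than the band admits) has no steady state
  ss <- detect_steady_state(map_series(t, 68 - t / 30))
  expect_false(ss$found)
})

test_that("step-response metrics capture overshoot, effectiveness, rise time", {
  # constant at target: no overshoot, fully effective, instant rise
  ser <- map_series(0:59, rep(68, 60))
  sr <- step_response_metrics(ser)
  expect_equal(sr$relative_overshoot, 0, tolerance = 1e-12)
  expect_equal(sr$effectiveness, 100, tolerance = 1e-12)
  expect_equal(sr$efficiency_rise_time, 0, tolerance = 1e-12)

  # max 78 against steady state 68: 14.71% relative overshoot
  ss <- list(value = 68, onset_time = 0, found = TRUE)
  ser <- map_series(0:10, c(40, 50, 78, rep(68, 8)))
  sr <- step_response_metrics(ser, ss)
  expect_equal(sr$relative_overshoot, 10 / 68 * 100, tolerance = 1e-9)
  expect_equal(sr$overshoot_mmHg, 10, tolerance = 1e-12)

  # in the +/-5 band half the time -> 50%
  t <- seq(0, 3600, by = 1)
  p <- ifelse(t < 1800, 50, 68)
  sr <- step_response_metrics(map_series(t, p),
                              list(value = 68, onset_time = 1800,
                                   found = TRUE))
  expect_equal(sr$effectiveness, 50, tolerance = 0.1)

  # without a steady state only effectiveness is defined
  sr <- step_response_metrics(map_series(0:10, 68 - (0:10)),
                              list(found = FALSE))
  expect_true(is.na(sr$relative_overshoot))
  expect_true(is.na(sr$efficiency_rise_time))
  expect_false(is.na(sr$effectiveness))
})

test_that("volume metrics are ratios and means of the flow columns", {
  rec <- data.frame(time_s = c(0, 60, 120),
                    q_infusion_mL_min = c(0, 100, 200),
                    q_hemorrhage_mL_min = c(50, 45, 40),
                    q_urine_mL_min = c(5, 5, 5))
  vm <- volume_metrics(rec)
  expect_equal(vm$average_infusion_rate, 100, tolerance = 1e-12)
  expect_equal(vm$volume_efficiency, (0 + 100) / (55 + 50),
               tolerance = 1e-12)
  dry <- rec
  dry$q_hemorrhage_mL_min <- 0; dry$q_urine_mL_min <- 0
  expect_warning(vm <- volume_metrics(dry), "zero total outflow")
  expect_true(is.na(vm$volume_efficiency))
})

test_that("areas to setpoint match the closed-form sums", {
  # at target: both areas zero
  am <- area_metrics(map_series(0:10 * 60, rep(68, 11)))
  expect_equal(am$area_above, 0, tolerance = 1e-12)
  expect_equal(am$area_below, 0, tolerance = 1e-12)
  # constant 78 for 10 min: (10/68)*10 min above
  am <- area_metrics(map_series(0:10 * 60, rep(78, 11)))
  expect_equal(am$area_above, 10 / 68 * 10, tolerance = 1e-9)
  expect_equal(am$area_below, 0, tolerance = 1e-12)
  # constant 58 for 34 min: exactly 5 min of deficit burden
  am <- area_metrics(map_series(0:34 * 60, rep(58, 35)))
  expect_equal(am$area_below, 5, tolerance = 1e-9)
})

test_that("signed area identity holds against the PE sum", {
  set.seed(13)
  for (i in 1:10) {
    t <- sort(stats::runif(60, 0, 3000))
    p <- 68 + stats::rnorm(60, 0, 8)
    ser <- map_series(t, p)
    am <- area_metrics(ser)
    pe <- performance_errors(ser)
    signed <- sum(pe[-1] * diff(t) / 60) / 100
    expect_equal(am$area_above - am$area_below, signed, tolerance = 1e-9)
  }
})

test_that("rise area truncates at 90% of target", {
  # linear rise 40 -> 68; 0.9*68 = 61.2 reached at a known time
  t <- seq(0, 600, by = 1)
  p <- 40 + (68 - 40) * t / 600
  ser <- map_series(t, p)
  ra <- rise_area_to_setpoint(ser)
  expect_true(ra$reached)
  idx <- which(p >= 61.2)[1]
  oracle <- area_metrics(map_series(t[1:idx], p[1:idx]))$area_below
  expect_equal(ra$rise_area, oracle, tolerance = 1e-12)
  # starting at 90% of target: zero burden
  expect_identical(rise_area_to_setpoint(map_series(0:5, rep(61.3, 6)))$rise_area,
                   0)
  # never reaching 90%: full-series area with a flag
  flat <- map_series(0:30 * 60, rep(50, 31))
  ra <- rise_area_to_setpoint(flat)
  expect_false(ra$reached)
  expect_equal(ra$rise_area, area_metrics(flat)$area_below,
               tolerance = 1e-12)
})

test_that("the report carries twelve metrics per scope", {
  rec <- data.frame(time_s = 0:299,
                    sensed_map_mmHg = c(seq(40, 68, length.out = 100),
                                        rep(68, 200)),
                    q_infusion_mL_min = 100,
                    q_hemorrhage_mL_min = 40, q_urine_mL_min = 5,
                    scenario_id = 1)
  rep <- performance_report(rec, target = 68)
  core <- c("mdpe", "mdape", "wobble", "divergence", "relative_overshoot",
            "effectiveness", "efficiency_rise_time", "volume_efficiency",
            "average_infusion_rate", "area_above", "area_below", "rise_area")
  expect_true(all(core %in% rep$metric[rep$scope == "scenario_1"]))
})
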