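test_that("gaze generator is deterministic and honours its contract", {
  p <- workload_profile("det", 30, fixation_rate = 2)
  a <- simulate_gaze(p, seed = 17)
  b <- simulate_gaze(p, seed = 17)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$events, b$truth$events)
  c2 <- simulate_gaze(p, seed = 18)
  expect_false(identical(a$recording$samples, c2$recording$samples))
  # infeasible rate is rejected up front
  expect_error(simulate_gaze(workload_profile("bad", 10, fixation_rate = 8)),
               "infeasible")
  # timestamps regular at the requested rate
  expect_equal(a$recording$nominal_rate, 100)
  expect_equal(nrow(a$recording$samples), 3000)
})

test_that("realized fixation rate converges to the profile rate", {
  p <- workload_profile("conv", 300, fixation_rate = 2)
  g <- simulate_gaze(p, noise_sd = 0, seed = 29)
  n_fix <- sum(g$truth$events$kind == "fixation")
  # within 2 standard errors of 600 at 300 s (renewal process, approx sqrt(n))
  expect_lt(abs(n_fix - 600), 2 * sqrt(600) + 5)
})

test_that("detector recovers generated fixation counts at low noise", {
  for (cfg in list(list(dur = 60, rate = 2, noise = 0, seed = 42),
                   list(dur = 120, rate = 2.5, noise = 0.05, seed = 9))) {
    p <- workload_profile("rec", cfg$dur, fixation_rate = cfg$rate)
    g <- simulate_gaze(p, noise_sd = cfg$noise, seed = cfg$seed)
    ev <- ivt_classify(g$recording)
    truth_n <- sum(g$truth$events$kind == "fixation")
    det_n <- sum(ev$kind == "fixation")
    expect_lt(abs(det_n - truth_n) / truth_n, 0.05)
  }
  # no injected intrusions and zero noise -> no detections
  g0 <- simulate_gaze(workload_profile("clean", 60), noise_sd = 0, seed = 3)
  expect_equal(nrow(detect_intrusions(g0$recording)), 0)
})

test_that("pupil generator determinism and degenerate band power", {
  p <- workload_profile("pp", 20, pupil_band_power = 0.03)
  a <- simulate_pupil(p, seed = 8)
  b <- simulate_pupil(p, seed = 8)
  expect_identical(a$series$diameter, b$series$diameter)
  # zero band power, zero noise: index vanishes (drift sits below 1 Hz)
  z <- simulate_pupil(workload_profile("z", 10, pupil_band_power = 0),
                      noise_sd = 0, seed = 2)
  m <- mpc(z$series)
  # residual is spectral leakage of the sub-band drift, far below
  # the index values any nonzero band power produces
  expect_lt(max(m$mpc), 0.02)
  # blink gaps appear at roughly the requested rate
  bl <- simulate_pupil(p, blink_rate = 12, seed = 4)
  expect_gt(sum(is.na(bl$series$diameter)), 0)
  expect_equal(nrow(bl$truth$blinks),
               12 * 20 / 60, tolerance = 4)
})

test_that("tracking generator reproduces control-strategy signatures", {
  tr <- simulate_pilot_tracking(n_steps = 3, seed = 4)
  expect_s3_class(tr, "tracking_trace")
  pm <- per_boundary_metrics(tr, NULL)
  # rising gain: aggressiveness and duty cycle increase every step
  expect_true(all(diff(pm$aggressiveness) > 0))
  expect_true(all(diff(pm$duty_cycle) > 0))
  # ideal-pursuit limit: zero error
  tri <- simulate_pilot_tracking(n_steps = 1, kp = Inf, seed = 1)
  expect_equal(tracking_error(tri)$rms, 0)
  # zero gain: error RMS equals the target RMS
  tr0 <- simulate_pilot_tracking(n_steps = 1, kp = 0, kd = 0, noise_sd = 0,
                                 seed = 1)
  expect_equal(tracking_error(tr0)$rms,
               sqrt(mean(sos_signal(sos_spec(), tr0$t)^2)),
               tolerance = 1e-9)
  # diverging configuration is caught
  expect_error(simulate_pilot_tracking(n_steps = 1, kp = 80, kd = 2,
                                       control_effectiveness = 50,
                                       noise_sd = 0, seed = 1),
               "unstable")
})

test_that("flight generator couples fixation rate to the dive profile", {
  phases <- phase_table(c("cruise", "dive", "cruise2"),
                        c(0, 60, 180), c(60, 180, 240))
  profs <- list(cruise = workload_profile("cruise", 1, fixation_rate = 1.2),
                dive = workload_profile("dive", 1, fixation_rate = 1.2),
                cruise2 = workload_profile("cruise2", 1, fixation_rate = 1.2))
  dives <- data.frame(start = 75, depth_ft = 6000, duration = 90)
  fl <- simulate_flight(phases, profs, dives, seed = 12)
  # determinism
  fl2 <- simulate_flight(phases, profs, dives, seed = 12)
  expect_identical(fl$gaze$samples, fl2$gaze$samples)
  # altitude is the raised-cosine profile: back to base at dive end
  expect_equal(fl$altitude$altitude_ft[1], 15000)
  alt_mid <- fl$altitude$altitude_ft[which.min(abs(fl$altitude$t - 120))]
  expect_equal(alt_mid, 9000, tolerance = 10)
  expect_equal(fl$altitude$altitude_ft[nrow(fl$altitude)], 15000,
               tolerance = 10)
  # no dives: flat altitude
  fl0 <- simulate_flight(phases, profs, seed = 12)
  expect_true(all(fl0$altitude$altitude_ft == 15000))
  # overlapping dives rejected
  bad <- data.frame(start = c(70, 100), depth_ft = c(5000, 5000),
                    duration = c(60, 60))
  expect_error(simulate_flight(phases, profs, bad), "overlap")
})
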