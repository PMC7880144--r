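sine_series <- function(freq, amp, duration = 1, rate = 100, baseline = 4) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  pupil_series(t, baseline + amp * sin(2 * pi * freq * t), rate = rate)
}

test_that("gap interpolation fills short gaps and leaves long ones", {
  t <- seq(0, 9.99, 0.01)
  d <- rep(4, 1000)
  d[301:310] <- NA          # 100 ms gap
  d[601:800] <- NA          # 2 s gap
  s <- pupil_series(t, d, rate = 100)
  out <- preprocess_pupil(s, max_gap = 0.5)
  expect_false(anyNA(out$diameter[301:310]))
  expect_equal(out$diameter[301:310], rep(4, 10))  # endpoints preserved
  expect_true(all(is.na(out$diameter[601:800])))
  # gap-free series is untouched
  s2 <- sine_series(2, 0.1, duration = 2)
  expect_identical(preprocess_pupil(s2)$diameter, s2$diameter)
})

test_that("spectral index recovers bin-centred sinusoids exactly", {
  # single-sided magnitude of a bin-centred 3 Hz tone is its amplitude
  for (A in c(0.1, 0.25, 0.5)) {
    m <- mpc(sine_series(3, A), buffer = NULL)
    expect_equal(m, A, tolerance = 1e-9)
  }
  # constant signal: zero after mean removal
  t <- seq(0, 0.99, 0.01)
  expect_equal(mpc(pupil_series(t, rep(4, 100), rate = 100), buffer = NULL), 0)
  # out-of-band 20 Hz tone leaks < 1% of the equal-amplitude in-band value
  in_band <- mpc(sine_series(3, 0.5), buffer = NULL)
  out_band <- mpc(sine_series(20, 0.5), buffer = NULL)
  expect_lt(out_band, 0.01 * in_band)
  # DC offsets do not change the index
  s <- sine_series(3, 0.2, baseline = 4)
  s_off <- pupil_series(s$t, s$diameter + 2, rate = 100)
  expect_equal(mpc(s, buffer = NULL), mpc(s_off, buffer = NULL),
               tolerance = 1e-9)
  # band edges are inclusive: 1 Hz and 5 Hz tones both count
  expect_equal(mpc(sine_series(1, 0.3), buffer = NULL), 0.3, tolerance = 1e-9)
  expect_equal(mpc(sine_series(5, 0.3), buffer = NULL), 0.3, tolerance = 1e-9)
})

test_that("buffered index is constant for a stationary tone and flags gaps", {
  s <- sine_series(3, 0.4, duration = 10)
  m <- mpc(s, buffer = 1)
  expect_equal(nrow(m), 10)
  expect_true(all(m$valid))
  expect_lt(diff(range(m$mpc)) / mean(m$mpc), 0.01)
  # a buffer containing missing samples is flagged invalid
  d <- s$diameter; d[250] <- NA
  m2 <- mpc(pupil_series(s$t, d, rate = 100), buffer = 1)
  expect_false(m2$valid[3])
  expect_true(all(m2$valid[-3]))
  # sampling rate must support the band
  slow <- pupil_series(seq(0, 9.5, 0.5), rep(4, 20), rate = 2)
  expect_error(mpc(slow), "twice")
})

test_that("index is monotone in the amplitude of an in-band component", {
  amps <- c(0.05, 0.1, 0.2, 0.4)
  vals <- vapply(amps, function(A) mpc(sine_series(2, A), buffer = NULL), 0)
  expect_true(all(diff(vals) > 0))
  # and linear: doubling amplitude doubles the index
  expect_equal(vals[3] / vals[2], 2, tolerance = 0.01)
})

test_that("generated band power is recovered monotonically across levels", {
  levels <- c(0.01, 0.03, 0.06)
  means <- vapply(seq_along(levels), function(i) {
    p <- workload_profile(paste0("L", i), 30, pupil_band_power = levels[i])
    sim <- simulate_pupil(p, seed = 21 + i)
    m <- mpc(sim$series)
    mean(m$mpc[m$valid])
  }, 0)
  expect_equal(cor(means, levels, method = "spearman"), 1)
})

test_that("condition summary reports means and ordering flags", {
  by_cond <- list(C1 = data.frame(mpc = c(1, 1.2), valid = TRUE),
                  C2 = data.frame(mpc = c(1.5, 1.7), valid = TRUE),
                  C3 = data.frame(mpc = c(2.5, 2.7), valid = TRUE))
  out <- mpc_condition_summary(by_cond)
  expect_equal(out$reference, "C3")
  expect_true(all(out$reference_exceeds))
  # ties give FALSE flags
  same <- list(C1 = c(1, 2), C2 = c(1, 2), C3 = c(1, 2))
  out2 <- mpc_condition_summary(same)
  expect_false(any(out2$reference_exceeds))
  # all-invalid condition warns and yields NA
  bad <- list(C1 = c(1, 2), C2 = numeric(0))
  expect_warning(out3 <- mpc_condition_summary(bad, reference = "C1"), "valid")
  expect_true(is.na(out3$means[["C2"]]))
})

test_that("pupil variability matches hand values and sampling theory", {
  t <- seq(0, 0.59, 0.01)
  expect_equal(pupil_sd(pupil_series(t, rep(3, 60), rate = 100)), 0)
  alt <- pupil_series(t, rep(c(2, 4), 30), rate = 100)
  expect_equal(pupil_sd(alt), sd(rep(c(2, 4), 30)))
  expect_equal(pupil_sd(alt), 1.0, tolerance = 0.01)
  set.seed(5)
  tt <- seq(0, 59.99, 0.01)
  g <- pupil_series(tt, pmax(0.5, 4 + rnorm(6000, sd = 0.3)), rate = 100)
  expect_equal(pupil_sd(g), 0.3, tolerance = 0.02)
  expect_error(pupil_sd(pupil_series(0, 4)), "insufficient")
})
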