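make_rec <- function(x, y = rep(0, length(x)), rate = 100) {
  t <- seq(0, by = 1 / rate, length.out = length(x))
  gaze_recording(t, x, y, nominal_rate = rate)
}

test_that("gaze velocity recovers known speeds and masks invalid windows", {
  # stationary gaze: zero speed at interior samples
  r <- make_rec(rep(1.5, 50))
  v <- gaze_velocity(r)
  expect_equal(unname(v[2:49]), rep(0, 48))
  expect_true(all(is.na(v[c(1, 50)])))

  # a 10 deg/s ramp in x at 100 Hz
  r2 <- make_rec(seq(0, by = 0.1, length.out = 100))
  v2 <- gaze_velocity(r2)
  expect_equal(unname(v2[2:99]), rep(10, 98), tolerance = 1e-9)

  # one invalid sample masks exactly the window positions touching it
  x <- seq(0, by = 0.1, length.out = 100)
  valid <- rep(TRUE, 100); valid[50] <- FALSE
  r3 <- gaze_recording(seq(0, 0.99, 0.01), x, rep(0, 100), valid = valid)
  v3 <- gaze_velocity(r3)
  expect_true(all(is.na(v3[49:51])))
  expect_false(anyNA(v3[c(2:48, 52:99)]))

  expect_error(gaze_velocity(make_rec(c(1, 2)), window = 4), "odd")
  one_valid <- gaze_recording(c(0, 0.01), c(1, NA), c(1, NA))
  expect_error(gaze_velocity(one_valid), "insufficient")
})

test_that("I-VT classifies constructed streams correctly", {
  # 2 s stationary gaze -> exactly one fixation, no saccade
  ev <- ivt_classify(make_rec(rep(0, 200)))
  expect_equal(sum(ev$kind == "fixation"), 1)
  expect_equal(sum(ev$kind == "saccade"), 0)

  # two 1 s epochs 5 deg apart joined by a 40 ms jump
  x <- c(rep(0, 100), seq(0, 5, length.out = 4), rep(5, 100))
  ev2 <- ivt_classify(make_rec(x))
  expect_equal(sum(ev2$kind == "fixation"), 2)
  expect_equal(sum(ev2$kind == "saccade"), 1)
  sac <- ev2[ev2$kind == "saccade", ]
  expect_equal(sac$amplitude, 5, tolerance = 0.15)
  fixes <- ev2[ev2$kind == "fixation", ]
  expect_equal(fixes$centroid_x, c(0, 5), tolerance = 0.1)

  # all-invalid input yields an empty event set with a warning
  allbad <- gaze_recording(seq(0, 0.99, 0.01), rep(NA_real_, 100),
                           rep(NA_real_, 100))
  expect_warning(ev3 <- ivt_classify(allbad), "invalid")
  expect_equal(nrow(ev3), 0)
})

test_that("I-VT equals brute-force thresholding plus run merging", {
  params <- ivt_params()
  for (seed in 1:25) {
    rec <- random_stream(seed)
    got <- ivt_classify(rec, params)
    want <- oracle_ivt(rec, params)
    expect_equal(got$kind, want$kind, info = paste("seed", seed))
    expect_equal(got$t_start, want$t_start, info = paste("seed", seed))
    expect_equal(got$t_end, want$t_end, info = paste("seed", seed))
    expect_equal(got$centroid_x, want$centroid_x, tolerance = 1e-12)
    expect_equal(got$centroid_y, want$centroid_y, tolerance = 1e-12)
    expect_equal(got$peak_velocity, want$peak_velocity, tolerance = 1e-12)
  }
})

test_that("events tile without overlap and fixation time grows with threshold", {
  for (seed in c(2, 12)) {
    rec <- random_stream(seed, duration = 3)
    ev <- ivt_classify(rec)
    ev <- ev[order(ev$t_start), ]
    expect_true(all(diff(ev$t_start) > 0))
    expect_true(all(ev$t_end[-nrow(ev)] <= ev$t_start[-1] + 1e-9))

    fix_time <- function(thr) {
      e <- ivt_classify(rec, ivt_params(velocity_threshold = thr))
      sum(e$t_end[e$kind == "fixation"] - e$t_start[e$kind == "fixation"])
    }
    times <- vapply(c(10, 20, 30, 60, 120), fix_time, 0)
    expect_true(all(diff(times) >= -1e-9))
  }
})

test_that("gap filling bridges short dropouts inside a fixation", {
  x <- rep(0, 200)
  valid <- rep(TRUE, 200); valid[100:103] <- FALSE  # 40 ms dropout
  rec <- gaze_recording(seq(0, 1.99, 0.01), x, rep(0, 200), valid = valid)
  ev <- ivt_classify(rec)
  expect_equal(sum(ev$kind == "fixation"), 1)
  # a dropout longer than max_gap_fill splits the fixation
  valid2 <- rep(TRUE, 200); valid2[95:115] <- FALSE  # 210 ms
  rec2 <- gaze_recording(seq(0, 1.99, 0.01), x, rep(0, 200), valid = valid2)
  ev2 <- ivt_classify(rec2)
  expect_equal(sum(ev2$kind == "fixation"), 2)
})

test_that("saccadic intrusions: excursion-and-return episodes only", {
  # constant x: nothing to find
  expect_equal(nrow(detect_intrusions(make_rec(rep(0, 300)))), 0)

  # square excursion of +1 deg lasting 200 ms, exact return
  x <- rep(0, 300); x[101:120] <- 1
  si <- detect_intrusions(make_rec(x))
  expect_equal(nrow(si), 1)
  expect_equal(si$t_start, 1.00, tolerance = 0.02)
  expect_equal(si$amplitude, 1, tolerance = 1e-6)

  # same excursion lasting 1000 ms: exceeds the return window
  x2 <- rep(0, 300); x2[101:200] <- 1
  expect_equal(nrow(detect_intrusions(make_rec(x2))), 0)

  # return faster than the minimum delay is not an intrusion
  x3 <- rep(0, 300); x3[101:104] <- 1  # back after 40 ms
  expect_equal(nrow(detect_intrusions(make_rec(x3))), 0)

  # sub-threshold excursion is ignored
  x4 <- rep(0, 300); x4[101:120] <- 0.3
  expect_equal(nrow(detect_intrusions(make_rec(x4))), 0)

  # an excursion in y alone is not a (horizontal) intrusion
  y5 <- rep(0, 300); y5[101:120] <- 1
  expect_equal(nrow(detect_intrusions(make_rec(rep(0, 300), y5))), 0)
})

test_that("SI detector achieves high sensitivity and low FDR on noisy streams", {
  g <- simulate_gaze(workload_profile("si", 300, fixation_rate = 1.5,
                                      intrusion_rate = 0.1),
                     noise_sd = 0.05, seed = 11)
  si <- detect_intrusions(g$recording)
  tru <- g$truth$events[g$truth$events$kind == "intrusion", ]
  conf <- si_confusion(tru$t_start, si$t_start)
  expect_gte(conf$sensitivity, 0.9)
  expect_lte(conf$fdr, 0.1)
  # detected intrusions never overlap
  si <- si[order(si$t_start), ]
  expect_true(all(si$t_end[-nrow(si)] <= si$t_start[-1] + 1e-9))
})

test_that("event rates and windowed counts conserve totals", {
  ev <- new_events_for_test(onsets = seq(0.5, 59.5, by = 2), kind = "fixation")
  expect_equal(event_rate(ev, "fixation", 60), 0.5)
  expect_equal(event_rate(ev, "fixation", 60, per = "minute"), 30)
  expect_equal(event_rate(new_events_for_test(numeric(), "fixation"),
                          "fixation", 60), 0)
  expect_error(event_rate(ev, "fixation", 0), "range")

  # ten events uniformly over [0, 50): one per 5 s window
  ev10 <- new_events_for_test(onsets = seq(2.5, 47.5, by = 5), kind = "fixation")
  wc <- windowed_counts(ev10, 5, 50, kind = "fixation")
  expect_equal(wc$count, rep(1L, 10))
  expect_false(any(wc$partial))

  # conservation over a partition, with a flagged partial window
  wc2 <- windowed_counts(ev, 7, 60, kind = "fixation")
  expect_equal(sum(wc2$count), 30)
  expect_true(wc2$partial[nrow(wc2)])
  # window equal to span: one total count
  wc3 <- windowed_counts(ev, 60, 60, kind = "fixation")
  expect_equal(wc3$count, 30L)
})
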