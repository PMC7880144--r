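#' Simulate a pupil-diameter series with known band power
#'
#' Diameter = baseline + slow drift + in-band component + white noise,
#' with blink gaps. The in-band component is a sum of random-phase
#' sinusoids at exactly 1, 2, 3, 4 and 5 Hz, each of amplitude
#' `pupil_band_power` — aligned with the spectral index's bin structure so
#' the generated band power is recovered exactly in expectation. Drift is
#' a 0.02 Hz sinusoid of 0.2 mm amplitude (below the 1 Hz band edge).
#' Blinks remove 100-300 ms of signal at the given rate.
#'
#' @param profiles A [workload_profile()] or list of them, played in order;
#'   `pupil_band_power` and `pupil_baseline` are used per interval.
#' @param rate Sampling rate, Hz (>= 10, i.e. twice the 5 Hz band edge).
#' @param blink_rate Blink gaps per minute (default 0).
#' @param noise_sd White measurement noise SD, mm (default 0.005).
#' @param eye Which eye to label the series with.
#' @param seed Integer RNG seed.
#' @return A list with `series` (a [pupil_series()]) and `truth`
#'   (per-interval band power and baseline, blink intervals, seed).
#' @export
simulate_pupil <- function(profiles, rate = 100, blink_rate = 0,
                           noise_sd = 0.005, eye = "left", seed = 1) {
  profiles <- as_profile_list(profiles)
  assert_number(rate, "rate", lower = 10)
  assert_number(blink_rate, "blink_rate", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  set.seed(as.integer(seed))

  durs <- vapply(profiles, `[[`, 0, "duration")
  offsets <- cumsum(c(0, durs))
  total <- offsets[length(offsets)]
  tg <- seq(0, total - 1 / rate, by = 1 / rate)
  d <- numeric(length(tg))

  truth_rows <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    sel <- tg >= offsets[k] & tg < offsets[k + 1]
    tt <- tg[sel]
    comp <- 0.2 * sin(2 * pi * 0.02 * tt + stats::runif(1, 0, 2 * pi))
    for (f in 1:5)
      comp <- comp + p$pupil_band_power *
        sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    d[sel] <- p$pupil_baseline + comp
    truth_rows[[k]] <- data.frame(label = p$label, t_start = offsets[k],
                                  t_end = offsets[k + 1],
                                  band_power = p$pupil_band_power,
                                  baseline = p$pupil_baseline)
  }
  if (noise_sd > 0) d <- d + stats::rnorm(length(d), sd = noise_sd)

  blink_df <- data.frame(t_start = numeric(), t_end = numeric())
  if (blink_rate > 0) {
    n_blinks <- stats::rpois(1, blink_rate * total / 60)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, total - 0.3))
      lens <- stats::runif(n_blinks, 0.1, 0.3)
      for (b in seq_len(n_blinks))
        d[tg >= onsets[b] & tg < onsets[b] + lens[b]] <- NA_real_
      blink_df <- data.frame(t_start = onsets, t_end = onsets + lens)
    }
  }

  series <- pupil_series(tg, d, eye = eye, rate = rate)
  list(series = series,
       truth = list(intervals = do.call(rbind, truth_rows),
                    blinks = blink_df, seed = seed))
}
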