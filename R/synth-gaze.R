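# Synthetic gaze generation: an alternating fixation/saccade renewal
# process sampled onto a regular grid, with optional square-wave saccadic
# intrusions and additive Gaussian position noise. Every generated event is
# exported as ground truth so detectors can be validated against it.

SACCADE_DURATION <- 0.040   # s; ballistic relocation time
MIN_FIX_DURATION <- 0.100   # s; truncation point of the duration draw
INTRUSION_MARGIN <- 0.120   # s; clean fixation margin around an excursion

# Draw a fixation duration with mean mu, truncated at MIN_FIX_DURATION.
# min + gamma(shape 2) keeps the mean exactly mu while bounding below.
draw_fix_duration <- function(mu) {
  if (mu <= MIN_FIX_DURATION)
    stopf("infeasible fixation rate: mean duration %.3f s <= minimum %.3f s",
          mu, MIN_FIX_DURATION)
  MIN_FIX_DURATION + stats::rgamma(1, shape = 2, scale = (mu - MIN_FIX_DURATION) / 2)
}

draw_saccade_amp <- function(mean_amp, sdlog = 0.35) {
  stats::rlnorm(1, meanlog = log(mean_amp) - sdlog^2 / 2, sdlog = sdlog)
}

reflect_into <- function(p, lim = 15) {
  while (abs(p) > lim) p <- sign(p) * (2 * lim) - p
  p
}

# Event-level generator. rate_at / amp_at are functions of time (s)
# returning the instantaneous fixation rate and mean saccade amplitude.
# Relocating saccades are redrawn if they would land back on the previous
# fixation position: an accidental out-and-back pair is indistinguishable
# from a saccadic intrusion, and intrusions are injected (and labeled)
# separately, so the ground truth must not contain unlabeled ones.
gen_gaze_events <- function(total, rate_at, amp_at) {
  t <- 0
  x <- 0; y <- 0
  prev_x <- NA_real_; prev_y <- NA_real_
  ev <- list()
  while (t < total) {
    r <- rate_at(t)
    mu_f <- 1 / r - SACCADE_DURATION
    d <- draw_fix_duration(mu_f)
    ev[[length(ev) + 1L]] <- list(kind = "fixation", t_start = t,
                                  t_end = min(t + d, total), x = x, y = y,
                                  amplitude = NA_real_)
    t <- t + d
    if (t >= total) break
    for (try in 1:20) {
      amp <- draw_saccade_amp(amp_at(t))
      theta <- stats::runif(1, 0, 2 * pi)
      x1 <- reflect_into(x + amp * cos(theta))
      y1 <- reflect_into(y + amp * sin(theta))
      revisits <- !is.na(prev_x) &&
        abs(x1 - prev_x) <= 0.5 && abs(y1 - prev_y) <= 0.5
      if (!revisits) break
    }
    prev_x <- x; prev_y <- y
    ev[[length(ev) + 1L]] <- list(kind = "saccade", t_start = t,
                                  t_end = min(t + SACCADE_DURATION, total),
                                  x = x1, y = y1,
                                  amplitude = sqrt((x1 - x)^2 + (y1 - y)^2))
    x <- x1; y <- y1
    t <- t + SACCADE_DURATION
  }
  do.call(rbind, lapply(ev, function(e)
    data.frame(kind = e$kind, t_start = e$t_start, t_end = e$t_end,
               x = e$x, y = e$y, amplitude = e$amplitude)))
}

# Sample the piecewise path onto the grid. During a saccade the position
# eases from the previous to the next fixation with a cosine ramp.
sample_gaze_path <- function(truth, tg) {
  x <- numeric(length(tg)); y <- numeric(length(tg))
  prev_x <- truth$x[1]; prev_y <- truth$y[1]
  for (k in seq_len(nrow(truth))) {
    sel <- tg >= truth$t_start[k] & tg < truth$t_end[k]
    if (!any(sel)) { if (truth$kind[k] == "saccade") { prev_x <- truth$x[k]; prev_y <- truth$y[k] }; next }
    if (truth$kind[k] == "fixation") {
      x[sel] <- truth$x[k]; y[sel] <- truth$y[k]
      prev_x <- truth$x[k]; prev_y <- truth$y[k]
    } else {
      u <- (tg[sel] - truth$t_start[k]) / (truth$t_end[k] - truth$t_start[k])
      w <- (1 - cos(pi * u)) / 2
      x[sel] <- prev_x + w * (truth$x[k] - prev_x)
      y[sel] <- prev_y + w * (truth$y[k] - prev_y)
      prev_x <- truth$x[k]; prev_y <- truth$y[k]
    }
  }
  list(x = x, y = y)
}

# Place square x-excursions inside sufficiently long fixations.
inject_intrusions <- function(truth, x, tg, n_wanted) {
  placed <- list()
  if (n_wanted < 1L) return(list(x = x, events = placed))
  fix <- truth[truth$kind == "fixation", , drop = FALSE]
  need <- function(dur) dur + 2 * INTRUSION_MARGIN
  for (i in seq_len(n_wanted)) {
    dur <- stats::runif(1, 0.15, 0.5)
    ok <- which(fix$t_end - fix$t_start >= need(dur))
    ok <- setdiff(ok, vapply(placed, `[[`, 0L, "fix_idx"))
    if (!length(ok)) next
    j <- ok[sample.int(length(ok), 1)]
    slack <- (fix$t_end[j] - fix$t_start[j]) - need(dur)
    onset <- fix$t_start[j] + INTRUSION_MARGIN + stats::runif(1, 0, slack)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.5)
    sel <- tg >= onset & tg < onset + dur
    x[sel] <- x[sel] + amp
    placed[[length(placed) + 1L]] <- list(t_start = onset, t_end = onset + dur,
                                          amplitude = abs(amp), fix_idx = j)
  }
  list(x = x, events = placed)
}

#' Simulate a gaze recording with known ground truth
#'
#' Generates an alternating fixation/saccade process: fixation durations
#' are drawn (gamma, shape 2, truncated at 100 ms) with mean set so the
#' realised fixation rate matches the profile in expectation; saccades
#' last 40 ms and relocate gaze by a lognormal amplitude in a uniform
#' random direction, reflected into a +/-15 degree field. Saccadic
#' intrusions are injected as square horizontal excursions (0.8-1.5 deg,
#' 150-500 ms — inside the 60-870 ms-return / >0.4 deg-deviation detection
#' envelope) centred within sufficiently long fixations, at the profile's
#' intrusion rate. Gaussian position noise is added last.
#'
#' @param profiles A [workload_profile()] or list of them, played in order.
#' @param rate Sampling rate, Hz (>= 50).
#' @param noise_sd Gaussian position noise SD, degrees (>= 0).
#' @param seed Integer RNG seed; the output is a pure function of
#'   (arguments, seed).
#' @return A list with `recording` (a [gaze_recording()]) and `truth` —
#'   a list with `events` (data.frame of true fixations, saccades and
#'   intrusions), `profiles`, and `seed`.
#' @export
simulate_gaze <- function(profiles, rate = 100, noise_sd = 0.05, seed = 1) {
  profiles <- as_profile_list(profiles)
  assert_number(rate, "rate", lower = 50)
  assert_number(noise_sd, "noise_sd", lower = 0)
  set.seed(as.integer(seed))

  durs <- vapply(profiles, `[[`, 0, "duration")
  offsets <- cumsum(c(0, durs))
  total <- offsets[length(offsets)]
  prof_at <- function(t) {
    i <- findInterval(t, offsets, rightmost.closed = FALSE)
    profiles[[min(max(i, 1L), length(profiles))]]
  }
  for (p in profiles)
    if (p$fixation_rate <= 0 ||
        1 / p$fixation_rate <= MIN_FIX_DURATION + SACCADE_DURATION)
      stopf("infeasible fixation rate %.2f /s in profile '%s'",
            p$fixation_rate, p$label)

  truth_ev <- gen_gaze_events(total,
                              rate_at = function(t) prof_at(t)$fixation_rate,
                              amp_at = function(t) prof_at(t)$saccade_amplitude_mean)

  tg <- seq(0, total - 1 / rate, by = 1 / rate)
  path <- sample_gaze_path(truth_ev, tg)
  x <- path$x; y <- path$y

  intr_events <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    if (p$intrusion_rate <= 0) next
    n_wanted <- stats::rpois(1, p$intrusion_rate * p$duration)
    in_prof <- truth_ev$t_start >= offsets[k] & truth_ev$t_start < offsets[k + 1]
    res <- inject_intrusions(truth_ev[in_prof, , drop = FALSE], x, tg, n_wanted)
    x <- res$x
    intr_events <- c(intr_events, res$events)
  }
  if (length(intr_events)) {
    intr_df <- do.call(rbind, lapply(intr_events, function(e)
      data.frame(kind = "intrusion", t_start = e$t_start, t_end = e$t_end,
                 x = NA_real_, y = NA_real_, amplitude = e$amplitude)))
    truth_ev <- rbind(truth_ev, intr_df)
    truth_ev <- truth_ev[order(truth_ev$t_start), , drop = FALSE]
    rownames(truth_ev) <- NULL
  }

  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = noise_sd)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }

  rec <- gaze_recording(tg, x, y, nominal_rate = rate)
  list(recording = rec,
       truth = list(events = truth_ev, profiles = profiles, seed = seed))
}
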