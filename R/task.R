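#' Sum-of-sines target specification
#'
#' The pursuit-tracking target is the pointwise sum of several sinusoids at
#' incommensurate frequencies, which keeps the pitch command unpredictable
#' to the pilot. The default is five components spanning 0.05-0.6 Hz with
#' decreasing amplitude — a conventional forcing-function profile; the
#' components are fully configurable.
#'
#' @param amplitude Component amplitudes, degrees (positive).
#' @param frequency Component frequencies, Hz (positive, distinct).
#' @param phase Component phases, radians.
#' @return A data.frame of class `sos_spec`.
#' @export
sos_spec <- function(amplitude = c(2.0, 1.4, 1.0, 0.7, 0.5),
                     frequency = c(0.053, 0.117, 0.229, 0.397, 0.583),
                     phase = rep(0, length(amplitude))) {
  if (length(amplitude) == 0L) stopf("empty sum-of-sines specification")
  if (length(frequency) != length(amplitude) || length(phase) != length(amplitude))
    stopf("amplitude, frequency and phase must have equal length")
  if (any(amplitude <= 0)) stopf("amplitudes must be positive")
  if (any(frequency <= 0) || anyDuplicated(frequency))
    stopf("frequencies must be positive and distinct")
  structure(data.frame(amplitude = amplitude, frequency = frequency,
                       phase = phase),
            class = c("sos_spec", "data.frame"))
}

#' Evaluate the sum-of-sines target
#'
#' @param spec An [sos_spec()].
#' @param t Increasing time grid, seconds.
#' @return Target pitch at each `t`, degrees.
#' @export
sos_signal <- function(spec, t) {
  stopifnot(inherits(spec, "sos_spec"))
  if (length(t) > 1L && any(diff(t) < 0)) stopf("time grid must be increasing")
  out <- numeric(length(t))
  for (i in seq_len(nrow(spec)))
    out <- out + spec$amplitude[i] *
      sin(2 * pi * spec$frequency[i] * t + spec$phase[i])
  out
}

#' Shrinking boundary schedule
#'
#' In the boundary-avoidance task the error boundaries hold for
#' `step_interval` seconds and then shrink by `shrink_fraction`; half-width
#' at time t is `initial_half_width * (1 - shrink_fraction)^floor(t /
#' step_interval)`. Defaults: 5 degrees initially, shrinking 20% every
#' 60 s, so the second minute runs at 4 degrees.
#'
#' @param initial_half_width Starting half-width, degrees (default 5).
#' @param shrink_fraction Fractional shrink per step, in (0, 1)
#'   (default 0.2).
#' @param step_interval Step length, seconds (default 60).
#' @return A list of class `boundary_schedule`.
#' @export
boundary_schedule <- function(initial_half_width = 5, shrink_fraction = 0.2,
                              step_interval = 60) {
  assert_number(initial_half_width, "initial_half_width", lower = 0, strict_lower = TRUE)
  assert_number(shrink_fraction, "shrink_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(step_interval, "step_interval", lower = 0, strict_lower = TRUE)
  structure(list(initial_half_width = initial_half_width,
                 shrink_fraction = shrink_fraction,
                 step_interval = step_interval),
            class = "boundary_schedule")
}

#' Boundary half-width at time t
#'
#' @param schedule A [boundary_schedule()].
#' @param t Time(s) since task start, seconds (>= 0).
#' @return Half-width(s), degrees.
#' @examples
#' sched <- boundary_schedule()
#' boundary_at(sched, c(30, 65, 125))  # 5, 4, 3.2
#' @export
boundary_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "boundary_schedule"))
  if (any(t < 0)) stopf("t must be non-negative")
  schedule$initial_half_width *
    (1 - schedule$shrink_fraction)^floor(t / schedule$step_interval)
}

#' Time-aligned tracking trace
#'
#' Target pitch, own pitch, stick deflection and the prevailing boundary
#' half-width on a common time grid.
#'
#' @param t Timestamps, seconds, strictly increasing.
#' @param target_pitch,own_pitch Pitch angles, degrees.
#' @param stick Stick deflection, degrees.
#' @param boundary_half_width Half-width at each t, degrees (may be `NA`
#'   when no boundaries are displayed).
#' @return A data.frame of class `tracking_trace`.
#' @export
tracking_trace <- function(t, target_pitch, own_pitch, stick,
                           boundary_half_width = NA_real_) {
  n <- length(t)
  if (length(target_pitch) != n || length(own_pitch) != n || length(stick) != n)
    stopf("all channels must have the same length as t")
  if (n > 1L && any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  structure(data.frame(t = t, target_pitch = target_pitch,
                       own_pitch = own_pitch, stick = stick,
                       boundary_half_width = rep_len(boundary_half_width, n)),
            class = c("tracking_trace", "data.frame"))
}

stick_rate <- function(stick, t, half_window = 1L) {
  central_diff(stick, t, half_window)
}

#' Duty cycle of stick movement
#'
#' Percentage of time with significant stick movement: the fraction of
#' samples (where the rate estimate is defined) whose absolute stick rate
#' exceeds `movement_threshold`, times 100. The rate uses the same
#' central-difference estimator as the gaze-velocity filter.
#'
#' @param stick Stick deflection series, degrees.
#' @param t Timestamps, seconds.
#' @param movement_threshold Deadband separating "significant" movement
#'   from holding, deg/s (default 1).
#' @return Duty cycle, percent.
#' @export
duty_cycle <- function(stick, t, movement_threshold = 1) {
  if (length(stick) < 2L) stopf("need >= 2 samples")
  assert_number(movement_threshold, "movement_threshold", lower = 0)
  r <- stick_rate(stick, t)
  r <- r[!is.na(r)]
  if (!length(r)) stopf("stick rate undefined everywhere")
  100 * mean(abs(r) > movement_threshold)
}

#' Aggressiveness of stick movement
#'
#' Root-mean-square of the stick movement speed, deg/s — the second
#' inceptor-workload metric. For a sinusoidal deflection `A sin(2 pi f t)`
#' this converges to `A * 2 * pi * f / sqrt(2)` at dense sampling.
#'
#' @inheritParams duty_cycle
#' @return RMS stick rate, deg/s.
#' @export
aggressiveness <- function(stick, t) {
  if (length(stick) < 2L) stopf("need >= 2 samples")
  r <- stick_rate(stick, t)
  r <- r[!is.na(r)]
  if (!length(r)) stopf("stick rate undefined everywhere")
  sqrt(mean(r^2))
}

#' Tracking error and boundary hits
#'
#' Error is own pitch minus target pitch at each instant; a boundary
#' violation occurs wherever |error| reaches the prevailing half-width.
#' Distinct violation episodes (contiguous runs of violating samples) are
#' counted as hits.
#'
#' @param trace A [tracking_trace()].
#' @return A list of class `tracking_error` with `error` (per-sample
#'   series), `mean_abs`, `rms`, `n_hits` (episodes), `time_in_violation`
#'   (seconds).
#' @export
tracking_error <- function(trace) {
  stopifnot(inherits(trace, "tracking_trace"))
  err <- trace$own_pitch - trace$target_pitch
  viol <- !is.na(trace$boundary_half_width) &
    abs(err) >= trace$boundary_half_width
  r <- rle(viol)
  n_hits <- sum(r$values)
  dt <- if (nrow(trace) > 1L) median_dt(trace$t) else 0
  structure(list(error = err, t = trace$t,
                 mean_abs = mean(abs(err)), rms = sqrt(mean(err^2)),
                 n_hits = n_hits, time_in_violation = sum(viol) * dt),
            class = "tracking_error")
}

#' @export
print.tracking_error <- function(x, ...) {
  cat(sprintf("Tracking error: mean|e| %.3f deg, RMS %.3f deg, %d boundary hit(s), %.1f s in violation\n",
              x$mean_abs, x$rms, x$n_hits, x$time_in_violation))
  invisible(x)
}

#' Per-boundary-step metric table
#'
#' Splits the trace into the schedule's consecutive full steps (60 s each
#' by default) and computes, per step: fixation and saccade counts (events
#' attributed by onset), duty cycle, aggressiveness, and median absolute
#' tracking error. Only complete steps are reported; a trace shorter than
#' one step yields an empty table with a warning.
#'
#' @param trace A [tracking_trace()].
#' @param events An `ocular_events` data.frame time-aligned with the trace
#'   (may be `NULL`).
#' @param schedule A [boundary_schedule()].
#' @param movement_threshold Deadband for [duty_cycle()], deg/s.
#' @return data.frame with one row per step: `step`, `t_start`, `t_end`,
#'   `half_width`, `n_fixations`, `n_saccades`, `duty_cycle`,
#'   `aggressiveness`, `median_abs_error`.
#' @export
per_boundary_metrics <- function(trace, events = NULL,
                                 schedule = boundary_schedule(),
                                 movement_threshold = 1) {
  stopifnot(inherits(trace, "tracking_trace"),
            inherits(schedule, "boundary_schedule"))
  # extent of the half-open sample grid: last sample covers one interval
  dt <- if (nrow(trace) > 1L) median_dt(trace$t) else 0
  span <- max(trace$t) - min(trace$t) + dt
  n_steps <- floor((span + 1e-9) / schedule$step_interval)
  if (n_steps < 1L) {
    warnf("trace shorter than one boundary step; empty metric table")
    return(data.frame(step = integer(), t_start = numeric(), t_end = numeric(),
                      half_width = numeric(), n_fixations = integer(),
                      n_saccades = integer(), duty_cycle = numeric(),
                      aggressiveness = numeric(), median_abs_error = numeric()))
  }
  t0 <- min(trace$t)
  rows <- lapply(seq_len(n_steps), function(k) {
    lo <- t0 + (k - 1) * schedule$step_interval
    hi <- lo + schedule$step_interval
    sel <- trace$t >= lo & trace$t < hi
    err <- trace$own_pitch[sel] - trace$target_pitch[sel]
    data.frame(
      step = k, t_start = lo, t_end = hi,
      half_width = boundary_at(schedule, lo - t0),
      n_fixations = count_onsets(events, "fixation", lo, hi),
      n_saccades = count_onsets(events, "saccade", lo, hi),
      duty_cycle = duty_cycle(trace$stick[sel], trace$t[sel], movement_threshold),
      aggressiveness = aggressiveness(trace$stick[sel], trace$t[sel]),
      median_abs_error = stats::median(abs(err)))
  })
  do.call(rbind, rows)
}
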