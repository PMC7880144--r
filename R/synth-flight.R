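#' Simulate an instrumented flight with phase-wise workload structure
#'
#' Generates gaze, pupil and altitude channels for a flight annotated into
#' phases (take-off, climb, cruise, maneuver, descent, landing, ...), each
#' phase carrying its own [workload_profile()]. During air-to-ground dives
#' the altitude follows a raised-cosine descend-and-recover profile —
#' smooth, with sign-correct vertical speed and a single extremum — and
#' the instantaneous fixation-rate parameter is raised in proportion to
#' the magnitude of the rate of descent, reproducing the
#' attention-tightening coupling seen in dive maneuvers.
#'
#' @param phases A [phase_table()].
#' @param profiles Named list of [workload_profile()], one per phase label
#'   (profile `duration` fields are ignored; phase intervals rule).
#' @param dives data.frame with columns `start` (s), `depth_ft`,
#'   `duration` (s); may be empty. Dives must not overlap.
#' @param coupling Fixation-rate increase per ft/s of descent-rate
#'   magnitude, (events/s)/(ft/s). Default 0.015.
#' @param base_altitude Altitude outside dives, ft.
#' @param rate Gaze/pupil sampling rate, Hz.
#' @param altitude_rate Altitude sampling rate, Hz (default 10).
#' @param noise_sd Gaze position noise SD, degrees.
#' @param seed Integer RNG seed.
#' @return A list with `gaze` (a [gaze_recording()]), `pupil`
#'   (a [pupil_series()]), `altitude` (data.frame `t, altitude_ft`),
#'   `phases`, and `truth` (events, per-phase profiles, dive table,
#'   coupling coefficient, seed).
#' @export
simulate_flight <- function(phases, profiles,
                            dives = data.frame(start = numeric(),
                                               depth_ft = numeric(),
                                               duration = numeric()),
                            coupling = 0.015, base_altitude = 15000,
                            rate = 100, altitude_rate = 10,
                            noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(phases, "phase_table"))
  if (!all(phases$label %in% names(profiles)))
    stopf("every phase label needs a profile; missing: %s",
          paste(setdiff(phases$label, names(profiles)), collapse = ", "))
  if (nrow(dives) > 1L) {
    d <- dives[order(dives$start), ]
    if (any(d$start[-1] < (d$start + d$duration)[-nrow(d)]))
      stopf("dive intervals must not overlap")
  }
  assert_number(coupling, "coupling", lower = 0)
  set.seed(as.integer(seed))

  total <- max(phases$end)

  # analytic |rate of descent| of the raised-cosine dive profile
  rod_at <- function(t) {
    out <- numeric(length(t))
    for (k in seq_len(nrow(dives))) {
      u <- (t - dives$start[k]) / dives$duration[k]
      inside <- u >= 0 & u <= 1
      out[inside] <- -(pi * dives$depth_ft[k] / dives$duration[k]) *
        sin(2 * pi * u[inside])
    }
    out
  }
  altitude_at <- function(t) {
    alt <- rep(base_altitude, length(t))
    for (k in seq_len(nrow(dives))) {
      u <- (t - dives$start[k]) / dives$duration[k]
      inside <- u >= 0 & u <= 1
      alt[inside] <- base_altitude -
        dives$depth_ft[k] / 2 * (1 - cos(2 * pi * u[inside]))
    }
    alt
  }
  phase_of <- function(t) {
    i <- findInterval(t, phases$start)
    i <- min(max(i, 1L), nrow(phases))
    phases$label[i]
  }
  rate_at <- function(t) {
    p <- profiles[[phase_of(t)]]
    p$fixation_rate + coupling * abs(rod_at(t))
  }
  amp_at <- function(t) profiles[[phase_of(t)]]$saccade_amplitude_mean

  truth_ev <- gen_gaze_events(total, rate_at, amp_at)
  tg <- seq(0, total - 1 / rate, by = 1 / rate)
  path <- sample_gaze_path(truth_ev, tg)
  x <- path$x; y <- path$y
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = noise_sd)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  gaze <- gaze_recording(tg, x, y, nominal_rate = rate)

  # pupil: per-phase band power/baseline over the phase intervals
  pupil_profiles <- lapply(seq_len(nrow(phases)), function(i) {
    p <- profiles[[phases$label[i]]]
    p$duration <- phases$duration[i]
    p
  })
  pup <- simulate_pupil(pupil_profiles, rate = rate,
                        seed = as.integer(seed) + 1L)

  ta <- seq(0, total - 1 / altitude_rate, by = 1 / altitude_rate)
  altitude <- data.frame(t = ta, altitude_ft = altitude_at(ta))

  list(gaze = gaze, pupil = pup$series, altitude = altitude, phases = phases,
       truth = list(events = truth_ev, profiles = profiles, dives = dives,
                    coupling = coupling, seed = seed))
}
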