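#' Workload profile for the synthetic-data generator
#'
#' One interval of a simulated session, encoding the statistical structure
#' of recorded behaviour at a given workload level: how often the eye
#' fixates, how large saccades are, how often saccadic intrusions occur,
#' how much 1-5 Hz power the pupil signal carries, and how active the
#' control stick is. Sequences of profiles encode condition contrasts
#' (e.g. low < medium < high load) or flight phases (take-off, cruise,
#' maneuver, landing).
#'
#' @param label Interval label (condition or phase name).
#' @param duration Interval length, seconds.
#' @param fixation_rate Target fixation rate, events/s.
#' @param saccade_amplitude_mean Mean saccade amplitude, degrees.
#' @param intrusion_rate Saccadic-intrusion rate, events/s.
#' @param pupil_band_power Amplitude of each in-band (1-5 Hz) pupil
#'   component, mm.
#' @param pupil_baseline Baseline pupil diameter, mm, in (1, 9).
#' @param stick_activity Stick-activity scale, deg/s.
#' @return A list of class `workload_profile`.
#' @export
workload_profile <- function(label, duration,
                             fixation_rate = 2,
                             saccade_amplitude_mean = 4,
                             intrusion_rate = 0,
                             pupil_band_power = 0.02,
                             pupil_baseline = 4,
                             stick_activity = 2) {
  assert_number(duration, "duration", lower = 0, strict_lower = TRUE)
  assert_number(fixation_rate, "fixation_rate", lower = 0)
  assert_number(saccade_amplitude_mean, "saccade_amplitude_mean", lower = 0)
  assert_number(intrusion_rate, "intrusion_rate", lower = 0)
  assert_number(pupil_band_power, "pupil_band_power", lower = 0)
  assert_number(pupil_baseline, "pupil_baseline", lower = 1, upper = 9,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(stick_activity, "stick_activity", lower = 0)
  structure(list(label = as.character(label), duration = duration,
                 fixation_rate = fixation_rate,
                 saccade_amplitude_mean = saccade_amplitude_mean,
                 intrusion_rate = intrusion_rate,
                 pupil_band_power = pupil_band_power,
                 pupil_baseline = pupil_baseline,
                 stick_activity = stick_activity),
            class = "workload_profile")
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "workload_profile")) return(list(profiles))
  if (!is.list(profiles) || !all(vapply(profiles, inherits, TRUE, "workload_profile")))
    stopf("`profiles` must be a workload_profile or a list of them")
  profiles
}
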