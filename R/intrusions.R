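#' Parameters of the saccadic-intrusion detector
#'
#' Saccadic intrusions are involuntary horizontal excursions of gaze away
#' from the fixated position followed by a return. The detector flags an
#' excursion when horizontal gaze departs from its pre-excursion reference
#' by more than `min_deviation` and comes back to within
#' `return_tolerance` of that reference after a delay inside
#' `[min_return, max_return]`.
#'
#' @param min_return,max_return Allowed return delay, seconds
#'   (defaults 0.060 and 0.870).
#' @param min_deviation Minimum horizontal departure, degrees (default 0.4).
#' @param return_tolerance How close to the reference the gaze must come
#'   back, degrees (default 0.4, i.e. the deviation threshold itself).
#' @param reference_window Length of the pre-onset window over which the
#'   reference position is averaged, seconds (default 0.100). The window
#'   must itself be stable (every sample within `return_tolerance` of its
#'   mean): an intrusion departs from a *fixated* position, and this
#'   stability requirement stops ordinary saccades from seeding episodes.
#' @param hold_window After the return, gaze must stay within
#'   `return_tolerance` of the reference for this long, seconds (default
#'   0.100) — "returned to the same position" means returned and stayed,
#'   not merely passed through.
#' @return A list of class `si_params`.
#' @export
si_params <- function(min_return = 0.060, max_return = 0.870,
                      min_deviation = 0.4, return_tolerance = 0.4,
                      reference_window = 0.100, hold_window = 0.100) {
  assert_number(min_return, "min_return", lower = 0, strict_lower = TRUE)
  assert_number(max_return, "max_return", lower = min_return, strict_lower = TRUE)
  assert_number(min_deviation, "min_deviation", lower = 0, strict_lower = TRUE)
  assert_number(return_tolerance, "return_tolerance", lower = 0, strict_lower = TRUE)
  assert_number(reference_window, "reference_window", lower = 0, strict_lower = TRUE)
  assert_number(hold_window, "hold_window", lower = 0)
  structure(list(min_return = min_return, max_return = max_return,
                 min_deviation = min_deviation,
                 return_tolerance = return_tolerance,
                 reference_window = reference_window,
                 hold_window = hold_window),
            class = "si_params")
}

#' Detect saccadic intrusions in the horizontal gaze channel
#'
#' Scans for excursion-and-return episodes. At each potential onset the
#' reference position is the mean valid gaze over the preceding
#' `reference_window`; an onset occurs where the *horizontal* offset
#' |x - reference_x| first exceeds `min_deviation` (the excursion measure
#' is X-only: intrusions are conjugate horizontal movements). The episode
#' is an intrusion when the first return of the gaze *position* (both
#' coordinates) to within `return_tolerance` of the reference happens
#' after a delay in `[min_return, max_return]` — a departure that never
#' comes back (an ordinary saccade) or comes back too late is not an
#' intrusion. Two stability conditions separate intrusions from saccade
#' chains that merely revisit the same horizontal position: the pre-onset
#' reference window must itself be fixated (every sample within
#' `return_tolerance` of its mean in both coordinates), and after the
#' return the gaze must hold within `return_tolerance` of the reference
#' for `hold_window`. Overlapping candidates are resolved by earliest
#' onset, then longest duration; the returned events never overlap.
#'
#' @param recording A [gaze_recording()] in degrees.
#' @param params An [si_params()].
#' @return An `ocular_events` data.frame (`kind = "intrusion"`) whose
#'   `amplitude` is the peak |x - reference| within the episode.
#' @export
detect_intrusions <- function(recording, params = si_params()) {
  stopifnot(inherits(recording, "gaze_recording"),
            inherits(params, "si_params"))
  s <- recording$samples
  t <- s$t
  x <- s$x
  y <- s$y
  n <- length(t)
  if (n < 3L || sum(s$valid) < 3L) return(new_ocular_events())

  cand <- list()
  i <- 2L
  while (i <= n) {
    if (!s$valid[i] || !s$valid[i - 1L]) { i <- i + 1L; next }
    win <- which(t >= t[i] - params$reference_window & t < t[i] & s$valid)
    if (!length(win)) { i <- i + 1L; next }
    ref_x <- mean(x[win]); ref_y <- mean(y[win])
    near_ref <- function(idx)
      abs(x[idx] - ref_x) <= params$return_tolerance &
      abs(y[idx] - ref_y) <= params$return_tolerance
    # reference window must look fixated, not mid-saccade
    if (!all(near_ref(win))) { i <- i + 1L; next }
    # onset: previous sample near reference, this one departed in x
    if (abs(x[i - 1L] - ref_x) <= params$min_deviation &&
        abs(x[i] - ref_x) > params$min_deviation) {
      j <- i + 1L
      ret <- NA_integer_
      while (j <= n && t[j] - t[i] <= params$max_return + 1e-12) {
        if (s$valid[j] && near_ref(j)) {
          ret <- j
          break
        }
        j <- j + 1L
      }
      if (!is.na(ret)) {
        dt_ret <- t[ret] - t[i]
        hold <- which(t >= t[ret] & t <= t[ret] + params$hold_window & s$valid)
        held <- all(near_ref(hold))
        if (dt_ret >= params$min_return - 1e-12 && held) {
          seg <- i:ret
          cand[[length(cand) + 1L]] <- list(
            t_start = t[i], t_end = t[ret],
            amplitude = max(abs(x[seg] - ref_x), na.rm = TRUE))
          i <- ret + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  if (!length(cand)) return(new_ocular_events())

  on <- vapply(cand, `[[`, 0, "t_start")
  off <- vapply(cand, `[[`, 0, "t_end")
  amp <- vapply(cand, `[[`, 0, "amplitude")
  ord <- order(on, -(off - on))
  keep <- logical(length(ord))
  last_end <- -Inf
  for (k in ord) {
    if (on[k] >= last_end) {
      keep[k] <- TRUE
      last_end <- off[k]
    }
  }
  new_ocular_events(kind = rep("intrusion", sum(keep)),
                    t_start = on[keep], t_end = off[keep],
                    centroid_x = NA_real_, centroid_y = NA_real_,
                    amplitude = amp[keep], peak_velocity = NA_real_)
}
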