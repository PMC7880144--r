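#' Angular gaze speed
#'
#' Per-sample angular speed (deg/s) of the 2-D gaze position, estimated by a
#' central difference across a symmetric window. A 3-sample window (the
#' default) differentiates across +/- 1 sample; wider windows trade temporal
#' resolution for noise suppression, which matters at 100 Hz where 2-point
#' differencing amplifies tracker jitter. Speeds are missing at the edges of
#' the recording and wherever the differencing window touches an invalid
#' sample.
#'
#' @param recording A [gaze_recording()].
#' @param window Odd window length in samples (>= 3).
#' @return Numeric vector of speeds (deg/s), one per sample, with `NA`
#'   where the speed is not defined; attribute `"t"` carries timestamps.
#' @export
gaze_velocity <- function(recording, window = 3L) {
  stopifnot(inherits(recording, "gaze_recording"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stopf("`window` must be an odd integer >= 3")
  s <- recording$samples
  if (sum(s$valid) < 2L)
    stopf("insufficient data: need at least 2 valid samples")
  h <- (window - 1L) %/% 2L
  vx <- central_diff(s$x, s$t, h)
  vy <- central_diff(s$y, s$t, h)
  speed <- sqrt(vx^2 + vy^2)
  speed[running_any(!s$valid, h)] <- NA_real_
  attr(speed, "t") <- s$t
  speed
}
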