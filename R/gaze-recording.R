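#' Timestamped gaze recording
#'
#' The canonical in-memory container for a gaze stream: one row per sample
#' with time (seconds since recording start), gaze position in degrees of
#' visual angle, optional left/right pupil diameters (mm), and a validity
#' flag. Pixel-native input is converted to degrees on construction (about
#' the scene-camera centre) using the supplied [camera_geometry()], because
#' every detection threshold downstream (30 deg/s velocity, 0.4 deg
#' deviation) is angular.
#'
#' Invalid samples keep their timestamp but have missing gaze coordinates.
#' Pupil diameters outside the physiological range (0, 12) mm are set to
#' missing with a warning. Missing values are always `NA`, never sentinel
#' zeros.
#'
#' @param t Numeric vector of timestamps, seconds, strictly increasing and
#'   non-negative.
#' @param x,y Gaze position per sample (degrees, or pixels when
#'   `native_units = "pixels"`).
#' @param pupil_left,pupil_right Optional pupil diameters, mm.
#' @param valid Optional logical validity flag; defaults to
#'   `!is.na(x) & !is.na(y)`.
#' @param nominal_rate Sampling rate in Hz; if `NULL`, inferred as the
#'   reciprocal of the median inter-sample interval.
#' @param native_units `"degrees"` (default) or `"pixels"`.
#' @param camera A [camera_geometry()]; required when `native_units` is
#'   `"pixels"`.
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples` (data.frame `t, x, y, pupil_left, pupil_right, valid`),
#'   `nominal_rate`, and `camera`.
#' @seealso [read_gaze_table()], [gaze_velocity()], [ivt_classify()]
#' @export
gaze_recording <- function(t, x, y, pupil_left = NULL, pupil_right = NULL,
                           valid = NULL, nominal_rate = NULL,
                           native_units = c("degrees", "pixels"),
                           camera = NULL) {
  native_units <- match.arg(native_units)
  n <- length(t)
  if (n == 0L) stopf("empty input: no gaze samples")
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t < 0))
    stopf("timestamps must be finite and non-negative")
  if (n > 1L && any(diff(t) <= 0))
    stopf("timestamps must be strictly increasing")
  if (length(x) != n || length(y) != n)
    stopf("x and y must have the same length as t")

  x <- as.numeric(x); y <- as.numeric(y)
  valid <- if (is.null(valid)) !is.na(x) & !is.na(y) else as.logical(valid)
  valid[is.na(valid)] <- FALSE
  valid <- valid & !is.na(x) & !is.na(y)
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_

  if (native_units == "pixels") {
    if (is.null(camera))
      stopf("pixel-native input requires a `camera` geometry")
    x <- pixels_to_degrees(x - camera$horizontal_resolution / 2, camera, "horizontal")
    y <- pixels_to_degrees(y - camera$vertical_resolution / 2, camera, "vertical")
  }

  clean_pupil <- function(p, name) {
    if (is.null(p)) return(rep(NA_real_, n))
    p <- as.numeric(p)
    bad <- !is.na(p) & (p <= 0 | p >= 12)
    if (any(bad)) {
      warnf("%d %s value(s) outside (0, 12) mm set to missing", sum(bad), name)
      p[bad] <- NA_real_
    }
    p
  }

  samples <- data.frame(
    t = as.numeric(t), x = x, y = y,
    pupil_left = clean_pupil(pupil_left, "pupil_left"),
    pupil_right = clean_pupil(pupil_right, "pupil_right"),
    valid = valid)

  if (is.null(nominal_rate)) {
    nominal_rate <- if (n > 1L) 1 / median_dt(samples$t) else NA_real_
  } else {
    assert_number(nominal_rate, "nominal_rate", lower = 0, strict_lower = TRUE)
  }

  structure(list(samples = samples, nominal_rate = nominal_rate,
                 camera = camera),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf("Gaze recording: %d samples, %.1f s, %.4g Hz nominal, %.1f%% valid\n",
              nrow(s), diff(range(s$t)), x$nominal_rate,
              100 * mean(s$valid)))
  invisible(x)
}

#' @export
summary.gaze_recording <- function(object, ...) {
  s <- object$samples
  out <- list(
    n = nrow(s),
    duration = diff(range(s$t)),
    nominal_rate = object$nominal_rate,
    prop_valid = mean(s$valid),
    x_range = range(s$x, na.rm = TRUE),
    y_range = range(s$y, na.rm = TRUE),
    pupil_left_mean = mean(s$pupil_left, na.rm = TRUE),
    pupil_right_mean = mean(s$pupil_right, na.rm = TRUE))
  class(out) <- "summary.gaze_recording"
  out
}

#' @export
print.summary.gaze_recording <- function(x, ...) {
  cat(sprintf("Gaze recording: %d samples over %.1f s at %.4g Hz (%.1f%% valid)\n",
              x$n, x$duration, x$nominal_rate, 100 * x$prop_valid))
  cat(sprintf("  x in [%.2f, %.2f] deg, y in [%.2f, %.2f] deg\n",
              x$x_range[1], x$x_range[2], x$y_range[1], x$y_range[2]))
  if (is.finite(x$pupil_left_mean) || is.finite(x$pupil_right_mean))
    cat(sprintf("  mean pupil diameter: left %.2f mm, right %.2f mm\n",
                x$pupil_left_mean, x$pupil_right_mean))
  invisible(x)
}

#' @export
plot.gaze_recording <- function(x, which = c("position", "scanpath"), ...) {
  which <- match.arg(which)
  s <- x$samples
  if (which == "position") {
    graphics::plot(s$t, s$x, type = "l", xlab = "time (s)",
                   ylab = "gaze (deg)", col = "steelblue",
                   ylim = range(c(s$x, s$y), na.rm = TRUE), ...)
    graphics::lines(s$t, s$y, col = "indianred")
    graphics::legend("topright", legend = c("x", "y"), lty = 1,
                     col = c("steelblue", "indianred"), bty = "n")
  } else {
    graphics::plot(s$x, s$y, type = "l", xlab = "x (deg)", ylab = "y (deg)",
                   col = grDevices::grey(0.5), ...)
  }
  invisible(x)
}
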