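#' Parameters of the velocity-threshold (I-VT) classifier
#'
#' @param velocity_threshold Angular speed separating fixation from saccade
#'   samples, deg/s. Default 30, the standard threshold for wearable
#'   trackers at ~100 Hz.
#' @param min_fixation_duration Shortest run emitted as a fixation,
#'   seconds. Default 0.060.
#' @param max_gap_fill Longest stretch of missing velocity bridged inside a
#'   run when both neighbours carry the same class, seconds. Default 0.075.
#' @param velocity_window Window of the speed estimator, samples (odd,
#'   >= 3); see [gaze_velocity()].
#' @return A list of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold = 30,
                       min_fixation_duration = 0.060,
                       max_gap_fill = 0.075,
                       velocity_window = 3L) {
  assert_number(velocity_threshold, "velocity_threshold", lower = 0, strict_lower = TRUE)
  assert_number(min_fixation_duration, "min_fixation_duration", lower = 0)
  assert_number(max_gap_fill, "max_gap_fill", lower = 0)
  structure(list(velocity_threshold = velocity_threshold,
                 min_fixation_duration = min_fixation_duration,
                 max_gap_fill = max_gap_fill,
                 velocity_window = as.integer(velocity_window)),
            class = "ivt_params")
}

new_ocular_events <- function(kind = character(), t_start = numeric(),
                              t_end = numeric(), centroid_x = numeric(),
                              centroid_y = numeric(), amplitude = numeric(),
                              peak_velocity = numeric()) {
  structure(data.frame(kind = kind, t_start = t_start, t_end = t_end,
                       centroid_x = centroid_x, centroid_y = centroid_y,
                       amplitude = amplitude, peak_velocity = peak_velocity),
            class = c("ocular_events", "data.frame"))
}

#' Classify fixations and saccades with the I-VT filter
#'
#' Velocity-threshold identification: every sample whose angular speed is
#' below `velocity_threshold` is a fixation sample, every sample at or
#' above it a saccade sample. Contiguous same-class runs become events;
#' stretches of undefined speed shorter than `max_gap_fill` are bridged
#' when the classes on both sides agree, so a single dropped sample does
#' not split a fixation. Fixation runs shorter than
#' `min_fixation_duration` are left unclassified. Events are half-open
#' intervals `[t_start, t_end)` and never overlap.
#'
#' Fixations carry the centroid (mean valid gaze position) of the run.
#' Saccades carry their peak speed and an amplitude equal to the angular
#' distance between the centroids of the bounding fixations (falling back
#' to the run's endpoint positions at the recording edges).
#'
#' @param recording A [gaze_recording()] in degrees.
#' @param params An [ivt_params()].
#' @return An `ocular_events` data.frame with columns
#'   `kind` (`"fixation"`/`"saccade"`), `t_start`, `t_end`, `centroid_x`,
#'   `centroid_y`, `amplitude`, `peak_velocity`.
#' @references Salvucci & Goldberg's taxonomy of identification algorithms
#'   places this filter in the velocity-threshold (I-VT) family.
#' @export
ivt_classify <- function(recording, params = ivt_params()) {
  stopifnot(inherits(recording, "gaze_recording"),
            inherits(params, "ivt_params"))
  s <- recording$samples
  if (!any(s$valid)) {
    warnf("all samples invalid; no events classified")
    return(new_ocular_events())
  }
  v <- gaze_velocity(recording, params$velocity_window)
  t <- s$t
  n <- length(t)
  dt <- median_dt(t)

  lab <- ifelse(is.na(v), "gap",
                ifelse(v < params$velocity_threshold, "fixation", "saccade"))

  # bridge short undefined stretches flanked by the same class
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != "gap") next
    if (k == 1L || k == length(r$values)) next
    gap_dur <- t[min(ends[k] + 1L, n)] - t[starts[k]]
    if (gap_dur <= params$max_gap_fill &&
        r$values[k - 1L] == r$values[k + 1L]) {
      lab[starts[k]:ends[k]] <- r$values[k - 1L]
    }
  }

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_list <- list()
  for (k in seq_along(r$values)) {
    kind <- r$values[k]
    if (kind == "gap") next
    i1 <- starts[k]; i2 <- ends[k]
    t0 <- t[i1]
    t1 <- if (i2 < n) t[i2 + 1L] else t[i2] + dt   # half-open tiling
    if (kind == "fixation" && (t1 - t0) < params$min_fixation_duration) next
    xs <- s$x[i1:i2]; ys <- s$y[i1:i2]
    ev_list[[length(ev_list) + 1L]] <- list(
      kind = kind, t_start = t0, t_end = t1,
      centroid_x = mean(xs, na.rm = TRUE),
      centroid_y = mean(ys, na.rm = TRUE),
      i1 = i1, i2 = i2,
      peak_velocity = if (kind == "saccade") max(v[i1:i2], na.rm = TRUE) else NA_real_)
  }
  if (!length(ev_list)) {
    warnf("no classifiable runs found")
    return(new_ocular_events())
  }

  ev <- new_ocular_events(
    kind = vapply(ev_list, `[[`, "", "kind"),
    t_start = vapply(ev_list, `[[`, 0, "t_start"),
    t_end = vapply(ev_list, `[[`, 0, "t_end"),
    centroid_x = vapply(ev_list, `[[`, 0, "centroid_x"),
    centroid_y = vapply(ev_list, `[[`, 0, "centroid_y"),
    amplitude = NA_real_,
    peak_velocity = vapply(ev_list, `[[`, 0, "peak_velocity"))

  # saccade amplitude: distance between bounding fixation centroids,
  # endpoint positions at the record edges
  is_sac <- ev$kind == "saccade"
  fix_idx <- which(ev$kind == "fixation")
  for (j in which(is_sac)) {
    prev_f <- fix_idx[fix_idx < j]
    next_f <- fix_idx[fix_idx > j]
    info <- ev_list[[j]]
    p0 <- if (length(prev_f))
      c(ev$centroid_x[max(prev_f)], ev$centroid_y[max(prev_f)])
    else c(s$x[info$i1], s$y[info$i1])
    p1 <- if (length(next_f))
      c(ev$centroid_x[min(next_f)], ev$centroid_y[min(next_f)])
    else c(s$x[info$i2], s$y[info$i2])
    ev$amplitude[j] <- sqrt(sum((p1 - p0)^2))
  }
  ev$amplitude[!is_sac] <- NA_real_
  attr(ev, "params") <- params
  ev
}

#' @export
print.ocular_events <- function(x, ...) {
  counts <- table(factor(x$kind, levels = c("fixation", "saccade", "intrusion")))
  cat(sprintf("Ocular events: %d fixations, %d saccades, %d intrusions\n",
              counts[["fixation"]], counts[["saccade"]], counts[["intrusion"]]))
  if (nrow(x)) NextMethod()
  invisible(x)
}

#' Write classified events as CSV
#'
#' @param events An `ocular_events` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "ocular_events"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, na = "")
  invisible(path)
}
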