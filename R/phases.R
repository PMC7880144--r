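#' Labeled phase intervals
#'
#' A phase table annotates a recording with labeled, non-overlapping,
#' half-open time intervals `[start, end)` — experimental conditions in a
#' simulator session or flight phases (take-off, climb, cruise, maneuver,
#' descent, landing). Phase durations are carried along so event counts can
#' be normalised to rates per phase.
#'
#' @param label Character vector of phase labels.
#' @param start,end Numeric vectors of interval bounds, seconds;
#'   `start < end` pairwise, intervals non-overlapping.
#'
#' @return A data.frame of class `phase_table` with columns
#'   `label, start, end, duration`.
#' @export
phase_table <- function(label, start, end) {
  if (length(label) != length(start) || length(start) != length(end))
    stopf("label, start and end must have equal length")
  if (length(label) == 0L) stopf("empty phase table")
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(start >= end))
    stopf("each phase must have start < end")
  ord <- order(start)
  label <- as.character(label)[ord]; start <- start[ord]; end <- end[ord]
  if (length(start) > 1L && any(start[-1] < end[-length(end)] - 1e-12))
    stopf("phase intervals must not overlap")
  structure(data.frame(label = label, start = start, end = end,
                       duration = end - start),
            class = c("phase_table", "data.frame"))
}

#' Read/write a phase table as CSV (`label,start_s,end_s`)
#'
#' @param path CSV path.
#' @return `read_phase_table`: a [phase_table()]; `write_phase_table`:
#'   `path` invisibly.
#' @export
read_phase_table <- function(path) {
  if (!file.exists(path)) stopf("phase file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(d)))
    stopf("phase table must have columns %s", paste(need, collapse = ","))
  phase_table(d$label, d$start_s, d$end_s)
}

#' @rdname read_phase_table
#' @param phases A [phase_table()].
#' @export
write_phase_table <- function(phases, path) {
  stopifnot(inherits(phases, "phase_table"))
  utils::write.csv(
    data.frame(label = phases$label, start_s = phases$start, end_s = phases$end),
    path, row.names = FALSE)
  invisible(path)
}

#' Slice a gaze recording by phase
#'
#' Cuts a recording into one segment per phase interval, keeping samples
#' with `t` in `[start, end)`. Labels and phase durations are preserved so
#' downstream rates can be normalised by the phase duration rather than the
#' (possibly shorter) span of retained samples. Intervals may overhang the
#' recorded span by at most one nominal sample interval.
#'
#' @param recording A [gaze_recording()].
#' @param phases A [phase_table()].
#' @return A named list of `gaze_recording` segments (one per phase, in
#'   phase order; names are the labels). Each carries attributes
#'   `phase_duration` and `phase_start`.
#' @export
slice_by_phase <- function(recording, phases) {
  stopifnot(inherits(recording, "gaze_recording"),
            inherits(phases, "phase_table"))
  s <- recording$samples
  tol <- 1 / recording$nominal_rate
  t_lo <- min(s$t) - tol
  t_hi <- max(s$t) + tol
  if (any(phases$start < t_lo) || any(phases$end > t_hi))
    stopf("phase interval(s) extend beyond the recording span")
  out <- vector("list", nrow(phases))
  for (i in seq_len(nrow(phases))) {
    sel <- s$t >= phases$start[i] & s$t < phases$end[i]
    if (!any(sel)) stopf("phase '%s' contains no samples", phases$label[i])
    seg <- recording
    seg$samples <- s[sel, , drop = FALSE]
    rownames(seg$samples) <- NULL
    attr(seg, "phase_duration") <- phases$duration[i]
    attr(seg, "phase_start") <- phases$start[i]
    out[[i]] <- seg
  }
  names(out) <- phases$label
  out
}
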