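#' Event rate over an interval
#'
#' Counts events of a kind whose *onset* falls in
#' `[t_start, t_start + duration)` and divides by the interval duration.
#' Attributing events by onset makes windowed counts over a partition sum
#' exactly to the whole-interval count.
#'
#' @param events An `ocular_events` data.frame.
#' @param kind Event kind to count (`"fixation"`, `"saccade"`,
#'   `"intrusion"`), or `NULL` for all.
#' @param duration Interval length, seconds (> 0).
#' @param t_start Interval onset, seconds.
#' @param per `"second"` (default) or `"minute"`.
#' @return Rate (events per second or per minute).
#' @export
event_rate <- function(events, kind = NULL, duration, t_start = 0,
                       per = c("second", "minute")) {
  per <- match.arg(per)
  assert_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- count_onsets(events, kind, t_start, t_start + duration)
  r <- n / duration
  if (per == "minute") r <- r * 60
  r
}

count_onsets <- function(events, kind, lo, hi) {
  if (is.null(events) || nrow(events) == 0L) return(0L)
  sel <- events$t_start >= lo & events$t_start < hi
  if (!is.null(kind)) sel <- sel & events$kind == kind
  sum(sel)
}

#' Event counts in consecutive windows
#'
#' Counts events by onset in consecutive half-open windows of fixed length
#' covering `[t_start, t_start + span)`. A trailing window shorter than
#' `window` is included and flagged `partial`.
#'
#' @inheritParams event_rate
#' @param window Window length, seconds (> 0).
#' @param span Total span covered, seconds.
#' @return data.frame with columns `window_start`, `window_end`, `count`,
#'   `partial`.
#' @export
windowed_counts <- function(events, window, span, kind = NULL, t_start = 0) {
  assert_number(window, "window", lower = 0, strict_lower = TRUE)
  assert_number(span, "span", lower = 0, strict_lower = TRUE)
  n_win <- ceiling((span - 1e-9) / window)
  starts <- t_start + (seq_len(n_win) - 1L) * window
  ends <- pmin(starts + window, t_start + span)
  counts <- vapply(seq_along(starts), function(i)
    count_onsets(events, kind, starts[i], ends[i]), integer(1))
  data.frame(window_start = starts, window_end = ends, count = counts,
             partial = (ends - starts) < window - 1e-12)
}
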