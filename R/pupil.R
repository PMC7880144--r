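#' Pupil-diameter series
#'
#' One eye's pupil-diameter signal. Diameters outside the physiological
#' range (0, 12) mm are set to missing with a warning; blinks and tracking
#' losses appear as `NA` runs.
#'
#' @param t Timestamps, seconds, strictly increasing.
#' @param diameter Pupil diameter, mm, `NA` where not measured.
#' @param eye `"left"` or `"right"`.
#' @param rate Sampling rate, Hz; inferred from the median inter-sample
#'   interval when `NULL`.
#' @return A list of class `pupil_series` with elements `t`, `diameter`,
#'   `eye`, `rate`.
#' @export
pupil_series <- function(t, diameter, eye = c("left", "right"), rate = NULL) {
  eye <- match.arg(eye)
  if (length(t) != length(diameter)) stopf("t and diameter lengths differ")
  if (length(t) < 1L) stopf("empty pupil series")
  if (length(t) > 1L && any(diff(t) <= 0))
    stopf("timestamps must be strictly increasing")
  diameter <- as.numeric(diameter)
  bad <- !is.na(diameter) & (diameter <= 0 | diameter >= 12)
  if (any(bad)) {
    warnf("%d diameter value(s) outside (0, 12) mm set to missing", sum(bad))
    diameter[bad] <- NA_real_
  }
  if (is.null(rate)) rate <- if (length(t) > 1L) 1 / median_dt(t) else NA_real_
  structure(list(t = as.numeric(t), diameter = diameter, eye = eye,
                 rate = rate),
            class = "pupil_series")
}

#' @export
print.pupil_series <- function(x, ...) {
  cat(sprintf("Pupil series (%s eye): %d samples, %.1f s at %.4g Hz, %.1f%% present\n",
              x$eye, length(x$t), diff(range(x$t)), x$rate,
              100 * mean(!is.na(x$diameter))))
  invisible(x)
}

#' Interpolate short gaps in a pupil series
#'
#' Gaps (runs of missing diameter) no longer than `max_gap` are filled by
#' linear interpolation between the bounding measurements; longer gaps —
#' typically blinks plus recovery, or sustained tracking loss — are left
#' missing so that spectral buffers overlapping them can be flagged invalid
#' rather than computed on fabricated data. Optionally clips diameters to a
#' physiological range.
#'
#' @param series A [pupil_series()].
#' @param max_gap Longest gap to interpolate, seconds (default 0.5).
#' @param clip Optional numeric range `c(lo, hi)` in mm; values outside are
#'   set to the bound.
#' @return A `pupil_series` with short gaps filled.
#' @export
preprocess_pupil <- function(series, max_gap = 0.5, clip = NULL) {
  stopifnot(inherits(series, "pupil_series"))
  assert_number(max_gap, "max_gap", lower = 0)
  d <- series$diameter
  t <- series$t
  na_runs <- rle(is.na(d))
  ends <- cumsum(na_runs$lengths)
  starts <- ends - na_runs$lengths + 1L
  for (k in seq_along(na_runs$values)) {
    if (!na_runs$values[k]) next
    i1 <- starts[k]; i2 <- ends[k]
    if (i1 == 1L || i2 == length(d)) next          # edge gaps stay missing
    gap_dur <- t[i2 + 1L] - t[i1 - 1L]
    if (gap_dur <= max_gap) {
      idx <- i1:i2
      d[idx] <- stats::approx(x = t[c(i1 - 1L, i2 + 1L)],
                              y = d[c(i1 - 1L, i2 + 1L)],
                              xout = t[idx])$y
    }
  }
  if (!is.null(clip)) d <- pmin(pmax(d, clip[1]), clip[2])
  out <- series
  out$diameter <- d
  out
}

#' Spectral pupillometric workload index (MPC)
#'
#' The Measure of Pupillary Cognition: per buffer, the pupil signal is
#' mean-removed, discrete-Fourier-transformed, and the single-sided
#' magnitudes of every bin whose centre frequency lies in `band`
#' (inclusive on both ends) are summed. With 1-second buffers at 100 Hz
#' the in-band bins sit exactly at 1, 2, 3, 4 and 5 Hz, so a bin-centred
#' sinusoid of amplitude A contributes A to the index. Buffers containing
#' missing samples are flagged invalid and their index is `NA`. Magnitudes
#' are scaled by 2/N (1/N at DC and Nyquist) so values are comparable
#' across buffer lengths.
#'
#' @param series A [pupil_series()] (run [preprocess_pupil()] first if the
#'   signal has gaps).
#' @param band Frequency band `c(f_lo, f_hi)`, Hz. Default `c(1, 5)`.
#' @param buffer Buffer length in seconds, or `NULL` to evaluate the whole
#'   series as a single buffer (full-signal mode).
#' @param window `"rectangular"` (default) or `"hann"` taper applied after
#'   mean removal.
#' @param demean Remove the buffer mean before the transform (default
#'   `TRUE`); with it off, spectral leakage from the DC component inflates
#'   the 1 Hz bin.
#' @return Full-signal mode: a single number. Buffered mode: a data.frame
#'   of class `mpc_series` with columns `buffer_start`, `mpc`, `valid` and
#'   attributes `band`, `buffer_length`, `window`.
#' @export
mpc <- function(series, band = c(1, 5), buffer = 1,
                window = c("rectangular", "hann"), demean = TRUE) {
  stopifnot(inherits(series, "pupil_series"))
  window <- match.arg(window)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stopf("`band` must be c(f_lo, f_hi) with 0 < f_lo < f_hi")
  rate <- series$rate
  if (!is.finite(rate) || rate < 2 * band[2])
    stopf("sampling rate (%g Hz) must be at least twice the upper band edge (%g Hz)",
          rate, band[2])

  one_buffer <- function(y) {
    if (anyNA(y)) return(NA_real_)
    N <- length(y)
    if (demean) y <- y - mean(y)
    if (window == "hann")
      y <- y * (0.5 - 0.5 * cos(2 * pi * seq_len(N) / (N + 1)))
    X <- stats::fft(y)
    nyq <- N %/% 2L
    k <- 0:nyq
    mag <- Mod(X[k + 1L]) / N
    scale2 <- k != 0L & !(N %% 2L == 0L & k == nyq)
    mag[scale2] <- 2 * mag[scale2]
    freq <- k * rate / N
    sel <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
    sum(mag[sel])
  }

  if (is.null(buffer)) return(one_buffer(series$diameter))

  assert_number(buffer, "buffer", lower = 0, strict_lower = TRUE)
  N <- floor(buffer * rate)
  if (N < 2L) stopf("buffer too short for the sampling rate")
  n_buf <- length(series$diameter) %/% N
  if (n_buf < 1L) stopf("series shorter than one buffer")
  vals <- vapply(seq_len(n_buf), function(b) {
    one_buffer(series$diameter[((b - 1L) * N + 1L):(b * N)])
  }, numeric(1))
  out <- data.frame(buffer_start = series$t[((seq_len(n_buf) - 1L) * N) + 1L],
                    mpc = vals, valid = !is.na(vals))
  structure(out, class = c("mpc_series", "data.frame"),
            band = band, buffer_length = buffer, window = window)
}

#' @export
plot.mpc_series <- function(x, ...) {
  graphics::plot(x$buffer_start, x$mpc, type = "h", lwd = 2,
                 col = ifelse(x$valid, "steelblue", "grey80"),
                 xlab = "buffer start (s)", ylab = "MPC (a.u.)", ...)
  invisible(x)
}

#' Write an MPC series as CSV (`buffer_start,mpc,valid`)
#'
#' @param x An `mpc_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mpc <- function(x, path) {
  stopifnot(inherits(x, "mpc_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-condition MPC summary and ordering check
#'
#' Averages the valid per-buffer index within each condition and reports,
#' for a designated high-load reference condition, whether its mean exceeds
#' each of the others — the per-participant ordering check used to ask
#' whether the hardest condition drives the pupillometric index highest.
#'
#' @param mpc_by_condition Named list mapping condition label to an
#'   `mpc_series` (or a numeric vector of per-buffer values).
#' @param reference Label of the high-load condition; defaults to the last
#'   element.
#' @return A list with `means` (named numeric), `reference`, and
#'   `reference_exceeds` (named logical, one per non-reference condition).
#'   Conditions with no valid buffer get `NA` mean with a warning.
#' @export
mpc_condition_summary <- function(mpc_by_condition, reference = NULL) {
  if (is.null(names(mpc_by_condition)))
    stopf("`mpc_by_condition` must be a named list")
  vals <- lapply(mpc_by_condition, function(m) {
    v <- if (inherits(m, "mpc_series") || is.data.frame(m)) m$mpc else as.numeric(m)
    v[is.finite(v)]
  })
  means <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1))
  if (anyNA(means))
    warnf("condition(s) with no valid buffers: %s",
          paste(names(means)[is.na(means)], collapse = ", "))
  reference <- reference %||% names(means)[length(means)]
  if (!reference %in% names(means)) stopf("unknown reference condition '%s'", reference)
  others <- setdiff(names(means), reference)
  flags <- means[reference] > means[others]
  names(flags) <- others
  list(means = means, reference = reference, reference_exceeds = flags)
}

#' Standard deviation of pupil diameter
#'
#' Sample standard deviation of the measured (non-missing) diameters —
#' the per-phase pupil variability summary.
#'
#' @param series A [pupil_series()].
#' @return Standard deviation, mm.
#' @export
pupil_sd <- function(series) {
  stopifnot(inherits(series, "pupil_series"))
  d <- series$diameter[!is.na(series$diameter)]
  if (length(d) < 2L) stopf("insufficient data: need >= 2 valid samples")
  stats::sd(d)
}
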