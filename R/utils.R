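# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("`%s` = %g is outside its valid range", name, x)
  invisible(x)
}

# Central-difference derivative over +/- half_window samples; NA at edges.
central_diff <- function(y, t, half_window = 1L) {
  n <- length(y)
  h <- as.integer(half_window)
  if (h < 1L) stopf("`half_window` must be >= 1")
  out <- rep(NA_real_, n)
  if (n >= 2L * h + 1L) {
    i <- (h + 1L):(n - h)
    out[i] <- (y[i + h] - y[i - h]) / (t[i + h] - t[i - h])
  }
  out
}

# TRUE where any position within +/- h samples is TRUE (edge-padded FALSE).
running_any <- function(flag, h) {
  n <- length(flag)
  out <- logical(n)
  for (k in -h:h) {
    idx <- seq_len(n) + k
    ok <- idx >= 1L & idx <= n
    out[ok] <- out[ok] | flag[idx[ok]]
  }
  out
}

median_dt <- function(t) {
  if (length(t) < 2L) stopf("need at least 2 timestamps")
  stats::median(diff(t))
}
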