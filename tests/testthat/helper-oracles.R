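# Independent oracles used to validate the implementation. These are
# deliberately written as naive, loop-based textbook computations so they
# share no code path with the package internals they check.

# Brute-force velocity-threshold classification: per-sample 3-point
# velocity, per-sample thresholding, sequential run merging.
oracle_ivt <- function(recording, params) {
  s <- recording$samples
  t <- s$t
  n <- nrow(s)
  dtm <- stats::median(diff(t))
  v <- rep(NA_real_, n)
  for (i in seq(2, n - 1))
    v[i] <- sqrt((s$x[i + 1] - s$x[i - 1])^2 + (s$y[i + 1] - s$y[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  lab <- ifelse(is.na(v), NA_character_,
                ifelse(v < params$velocity_threshold, "fixation", "saccade"))
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (is.na(lab[i])) { i <- i + 1L; next }
    j <- i
    while (j < n && identical(lab[j + 1L], lab[i])) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(kind = lab[i], i1 = i, i2 = j)
    i <- j + 1L
  }
  ev <- list()
  for (r in runs) {
    t0 <- t[r$i1]
    t1 <- if (r$i2 < n) t[r$i2 + 1L] else t[r$i2] + dtm
    if (r$kind == "fixation" && (t1 - t0) < params$min_fixation_duration) next
    ev[[length(ev) + 1L]] <- data.frame(
      kind = r$kind, t_start = t0, t_end = t1,
      centroid_x = mean(s$x[r$i1:r$i2]), centroid_y = mean(s$y[r$i1:r$i2]),
      peak_velocity = if (r$kind == "saccade") max(v[r$i1:r$i2]) else NA_real_)
  }
  do.call(rbind, ev)
}

# Textbook one-way ANOVA via explicit sums of squares.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  N <- length(all_v)
  k <- length(groups)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE),
       eta = ssb / (ssb + ssw), ssb = ssb, ssw = ssw,
       sst = sum((all_v - gm)^2))
}

# Welch statistic and Satterthwaite df from the printed formulas.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tt, df = df,
       p = 2 * stats::pt(-abs(tt), df))
}

# Pearson r from the product-moment formula.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Match detected intrusions against generator truth by onset time.
si_confusion <- function(truth_onsets, detected_onsets, tol = 0.05) {
  if (!length(truth_onsets))
    return(list(sensitivity = NA_real_,
                fdr = if (length(detected_onsets)) 1 else 0))
  sens <- mean(vapply(truth_onsets, function(on)
    any(abs(detected_onsets - on) < tol), TRUE))
  fdr <- if (length(detected_onsets))
    mean(vapply(detected_onsets, function(on)
      !any(abs(truth_onsets - on) < tol), TRUE))
  else 0
  list(sensitivity = sens, fdr = fdr)
}

# A gap-free random gaze stream alternating quiet and jumpy stretches,
# for oracle-equivalence property tests.
random_stream <- function(seed, duration = 2, rate = 100) {
  set.seed(seed)
  n <- duration * rate
  t <- seq(0, by = 1 / rate, length.out = n)
  # random-walk position with occasional large jumps
  steps_x <- stats::rnorm(n, sd = 0.03)
  steps_y <- stats::rnorm(n, sd = 0.03)
  jumps <- which(stats::runif(n) < 0.02)
  steps_x[jumps] <- steps_x[jumps] + sample(c(-1, 1), length(jumps), TRUE) *
    stats::runif(length(jumps), 1, 4)
  gaze_recording(t, cumsum(steps_x), cumsum(steps_y), nominal_rate = rate)
}

# Minimal event table for rate/window arithmetic tests.
new_events_for_test <- function(onsets, kind) {
  n <- length(onsets)
  data.frame(kind = rep(kind, n), t_start = onsets,
             t_end = onsets + 0.1, centroid_x = rep(NA_real_, n),
             centroid_y = rep(NA_real_, n), amplitude = rep(NA_real_, n),
             peak_velocity = rep(NA_real_, n))
}
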