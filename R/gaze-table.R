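#' Column-mapping dialect for delimited gaze exports
#'
#' Tracker exports differ in column names, delimiters, time units and gaze
#' units; a dialect records the mapping once so files can be ingested
#' reproducibly. Because exports do not declare whether gaze is in pixels
#' or degrees, the dialect must state it explicitly.
#'
#' @param time,x,y Names of the required columns.
#' @param pupil_left,pupil_right,validity Names of optional columns
#'   (`NULL` if absent).
#' @param units Gaze units in the file: `"degrees"` or `"pixels"`.
#' @param time_unit `"s"`, `"ms"` or `"us"`.
#' @param sep Field separator; `","` or `"\t"`.
#'
#' @return A list of class `gaze_dialect`.
#' @export
gaze_dialect <- function(time = "t", x = "x", y = "y",
                         pupil_left = NULL, pupil_right = NULL,
                         validity = NULL,
                         units = c("degrees", "pixels"),
                         time_unit = c("s", "ms", "us"),
                         sep = ",") {
  structure(list(time = time, x = x, y = y,
                 pupil_left = pupil_left, pupil_right = pupil_right,
                 validity = validity,
                 units = match.arg(units),
                 time_unit = match.arg(time_unit),
                 sep = sep),
            class = "gaze_dialect")
}

#' Read a dialect from a YAML or JSON file
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file whose keys match
#'   the arguments of [gaze_dialect()]. Unknown keys are rejected.
#' @return A `gaze_dialect`.
#' @export
read_gaze_dialect <- function(path) {
  if (!file.exists(path)) stopf("dialect file not found: %s", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  # YAML 1.1 parses bare `y`/`n` as booleans; map key and column names back
  names(spec)[names(spec) == "TRUE"] <- "y"
  for (field in c("time", "x", "y", "pupil_left", "pupil_right", "validity"))
    if (isTRUE(spec[[field]])) spec[[field]] <- "y"
    else if (isFALSE(spec[[field]])) spec[[field]] <- "n"
  known <- names(formals(gaze_dialect))
  unknown <- setdiff(names(spec), known)
  if (length(unknown))
    stopf("unknown dialect key(s): %s", paste(unknown, collapse = ", "))
  do.call(gaze_dialect, spec)
}

time_scale <- function(unit) switch(unit, s = 1, ms = 1e-3, us = 1e-6)

#' Read a delimited gaze export into a gaze recording
#'
#' Parses a CSV/TSV gaze export using a column-mapping dialect. Rows whose
#' time cell fails numeric parsing (or with duplicated timestamps after the
#' first) are skipped with a warning; rows whose gaze cells fail parsing are
#' kept but marked invalid, so parsed + invalid + skipped always accounts
#' for every file row. Pixel-native positions are converted to degrees
#' about the camera centre.
#'
#' @param path Path to the delimited file.
#' @param dialect A [gaze_dialect()] or path to one.
#' @param camera [camera_geometry()]; required for pixel-native files.
#' @param nominal_rate Declared sampling rate (Hz); inferred from the median
#'   inter-sample interval when `NULL`.
#'
#' @return A [gaze_recording()] with attribute `row_counts`
#'   (`parsed`, `invalid`, `skipped`).
#' @export
read_gaze_table <- function(path, dialect = gaze_dialect(), camera = NULL,
                            nominal_rate = NULL) {
  if (is.character(dialect)) dialect <- read_gaze_dialect(dialect)
  stopifnot(inherits(dialect, "gaze_dialect"))
  if (!file.exists(path)) stopf("gaze file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stopf("empty input: %s has no data rows", path)
  need <- c(dialect$time, dialect$x, dialect$y)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  t <- num(dialect$time) * time_scale(dialect$time_unit)
  x <- num(dialect$x)
  y <- num(dialect$y)
  pl <- if (!is.null(dialect$pupil_left) && dialect$pupil_left %in% names(raw))
    num(dialect$pupil_left) else NULL
  pr <- if (!is.null(dialect$pupil_right) && dialect$pupil_right %in% names(raw))
    num(dialect$pupil_right) else NULL
  vflag <- if (!is.null(dialect$validity) && dialect$validity %in% names(raw)) {
    v <- raw[[dialect$validity]]
    tolower(trimws(v)) %in% c("1", "true", "t", "valid", "yes")
  } else rep(TRUE, nrow(raw))

  n_rows <- nrow(raw)
  keep <- !is.na(t)
  # duplicate timestamps: keep the first occurrence
  dup <- duplicated(t) & keep
  keep <- keep & !dup
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warnf("skipped %d row(s) with unparseable or duplicate timestamps", n_skipped)

  t <- t[keep]; x <- x[keep]; y <- y[keep]
  pl <- pl[keep]; pr <- pr[keep]; vflag <- vflag[keep]
  ord <- order(t)
  t <- t[ord]; x <- x[ord]; y <- y[ord]
  pl <- pl[ord]; pr <- pr[ord]; vflag <- vflag[ord]

  valid <- vflag & !is.na(x) & !is.na(y)
  rec <- gaze_recording(t - t[1], x, y, pupil_left = pl, pupil_right = pr,
                        valid = valid, nominal_rate = nominal_rate,
                        native_units = dialect$units, camera = camera)
  attr(rec, "row_counts") <- c(parsed = sum(valid),
                               invalid = sum(!valid),
                               skipped = n_skipped)
  rec
}

#' Write a gaze recording as CSV
#'
#' Writes the canonical sample table (`t,x,y,pupil_left,pupil_right,valid`,
#' degrees and seconds) so that [read_gaze_table()] with the default dialect
#' round-trips it.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  utils::write.csv(recording$samples, path, row.names = FALSE, na = "")
  invisible(path)
}
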