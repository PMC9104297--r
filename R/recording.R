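#' Multi-channel EDA recording
#'
#' A recording holds simultaneous skin conductance series (microsiemens) from
#' one subject at several body sites, sampled at a common rate.
#'
#' @param samples Numeric matrix, one column per site, one row per time
#'   point; values in microsiemens.
#' @param fs Sampling rate in Hz.
#' @param sites Character vector of unique site labels, one per column.
#' @param subject_id Subject identifier.
#' @param t0 Start time of the first sample in seconds.
#' @param allow_negative Permit negative conductance values (only meaningful
#'   for artifact-distorted traces, e.g. simulated electrode motion).
#'
#' @return An object of class `eda_recording`: a list with elements
#'   `subject_id`, `fs`, `sites`, `samples`, `t0`.
#' @export
#' @examples
#' rec <- eda_recording(cbind(finger = c(5, 5.1, 5.2), foot = c(4, 4, 4.1)),
#'                      fs = 8, subject_id = "s01")
#' rec$sites
eda_recording <- function(samples, fs, sites = colnames(samples),
                          subject_id = "subject", t0 = 0,
                          allow_negative = FALSE) {
  samples <- as.matrix(samples)
  if (is.null(sites)) stop("site labels are required", call. = FALSE)
  colnames(samples) <- sites
  rec <- structure(list(subject_id = subject_id, fs = fs, sites = sites,
                        samples = samples, t0 = t0),
                   class = "eda_recording")
  validate_recording(rec, allow_negative = allow_negative)
  rec
}

#' Validate an EDA recording
#'
#' Checks the structural invariants: at least two samples, positive sampling
#' rate, finite values, unique site labels, and non-negative conductance
#' unless `allow_negative` flags the recording as artifact-distorted.
#'
#' @param rec An `eda_recording`.
#' @inheritParams eda_recording
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec, allow_negative = FALSE) {
  if (!inherits(rec, "eda_recording")) stop("not an eda_recording", call. = FALSE)
  if (!(is.numeric(rec$fs) && length(rec$fs) == 1 && rec$fs > 0))
    stop("fs must be a positive scalar", call. = FALSE)
  if (nrow(rec$samples) < 2) stop("recording needs at least 2 samples", call. = FALSE)
  if (length(rec$sites) < 1) stop("recording needs at least one site", call. = FALSE)
  if (anyDuplicated(rec$sites)) stop("site labels must be unique", call. = FALSE)
  if (ncol(rec$samples) != length(rec$sites))
    stop("one sample column per site is required", call. = FALSE)
  if (!all(is.finite(rec$samples)))
    stop("conductance values must be finite", call. = FALSE)
  if (!allow_negative && any(rec$samples < 0))
    stop("negative conductance; pass allow_negative = TRUE for ",
         "artifact-distorted traces", call. = FALSE)
  invisible(rec)
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("<eda_recording> subject %s: %d sites x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$sites), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  sites:", paste(x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eda_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read a multi-channel EDA recording from delimited text
#'
#' Expects a header line naming the columns. A time column, if present, is
#' informative only: the sampling rate `fs` is authoritative.
#'
#' @param path Path to a comma- or semicolon-delimited text file.
#' @param fs Sampling rate in Hz.
#' @param site_columns Names of the conductance columns to load, in the
#'   desired order.
#' @param subject_id Subject identifier attached to the recording.
#' @param allow_negative Permit negative (artifact-distorted) values.
#' @return An [eda_recording()].
#' @export
read_recording <- function(path, fs, site_columns, subject_id = "subject",
                           allow_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(";", first, fixed = TRUE)) ";" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(site_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- lapply(site_columns, function(cn) {
    v <- tab[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0)
      stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                   cn, bad[1]), call. = FALSE)
    num
  })
  samples <- do.call(cbind, cols)
  colnames(samples) <- site_columns
  t0 <- if ("time_s" %in% names(tab)) as.numeric(tab$time_s[1]) else 0
  eda_recording(samples, fs = fs, sites = site_columns,
                subject_id = subject_id, t0 = t0,
                allow_negative = allow_negative)
}

#' Write a recording as comma-separated text
#'
#' Writes a header row, a `time_s` column (seconds from `t0` at `1/fs`
#' spacing) and one column per site.
#'
#' @param rec An `eda_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec, allow_negative = TRUE)
  n <- nrow(rec$samples)
  tab <- data.frame(time_s = rec$t0 + (0:(n - 1)) / rec$fs)
  for (s in rec$sites) tab[[s]] <- rec$samples[, s]
  ok <- tryCatch({
    utils::write.csv(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("I/O error writing ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Stage annotations
#'
#' Builds a validated stage-annotation table from labels and interval bounds,
#' or from a stage plan of `(stage, duration)` pairs laid end to end.
#'
#' @param stage Character vector of stage labels.
#' @param start_s,end_s Interval bounds in seconds.
#' @return A `data.frame` with columns `stage`, `start_s`, `end_s`, ordered
#'   by `start_s`, of class `eda_annotations`.
#' @export
#' @examples
#' stage_annotations(c("baseline", "scwt"), c(0, 120), c(120, 240))
stage_annotations <- function(stage, start_s, end_s) {
  ann <- data.frame(stage = as.character(stage),
                    start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s),
                    stringsAsFactors = FALSE)
  bad <- which(!(ann$end_s > ann$start_s))
  if (length(bad) > 0)
    stop("validation error: end_s <= start_s at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  ann <- ann[order(ann$start_s), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1) {
    ovl <- which(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-9)
    if (length(ovl) > 0)
      stop("validation error: overlapping annotations at row(s) ",
           paste(ovl, collapse = ", "), " and ",
           paste(ovl + 1, collapse = ", "), call. = FALSE)
  }
  class(ann) <- c("eda_annotations", "data.frame")
  ann
}

#' The default four-stage experimental plan
#'
#' Four consecutive 120 s stages: supine rest (baseline), Stroop colour-word
#' test (scwt, cognitive stress), walking at 3 mph, and one-handed dumbbell
#' lifting (weightlifting).
#'
#' @return A data.frame with columns `stage` and `duration_s`.
#' @export
default_stage_plan <- function() {
  data.frame(stage = c("baseline", "scwt", "walking", "weightlifting"),
             duration_s = c(120, 120, 120, 120),
             stringsAsFactors = FALSE)
}

#' @rdname stage_annotations
#' @param plan A stage plan (`stage`, `duration_s` columns), e.g.
#'   [default_stage_plan()].
#' @param t0 Start time of the first stage in seconds.
#' @export
annotations_from_plan <- function(plan = default_stage_plan(), t0 = 0) {
  ends <- t0 + cumsum(plan$duration_s)
  starts <- c(t0, ends[-length(ends)])
  stage_annotations(plan$stage, starts, ends)
}

#' Read stage annotations from CSV
#'
#' Expects columns `stage`, `start_s`, `end_s`. Rows are returned sorted by
#' `start_s`; inverted or overlapping intervals raise a validation error
#' naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return An annotation table, see [stage_annotations()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "start_s", "end_s")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stage_annotations(tab$stage, tab$start_s, tab$end_s)
}

#' @rdname read_annotations
#' @param ann An annotation table.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("stage", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
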