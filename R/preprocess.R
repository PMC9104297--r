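#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero-phase), so the effective magnitude response is the square of the
#' single-pass response and SCR onset latencies are not shifted. Edge
#' handling: the line through the first and last sample (which a zero-phase
#' unit-DC-gain filter passes unchanged) is removed first, and the residual
#' is padded by odd-symmetric reflection over several settling times of the
#' slowest filter pole, so start-up transients are on the scale of the local
#' fluctuation, not of the conductance level.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (single pass).
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist rate.
#' @return Filtered series, same length as `x`. DC gain is 1.
#' @export
#' @examples
#' lowpass_filter(rep(5, 100), fs = 8, order = 6, cutoff_hz = 0.6)[50]
lowpass_filter <- function(x, fs, order = 6, cutoff_hz = 0.6) {
  if (!all(is.finite(x))) stop("validation error: non-finite samples", call. = FALSE)
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("validation error: cutoff must lie in (0, fs/2)", call. = FALSE)
  n <- length(x)
  if (n <= 3 * order)
    stop("validation error: series too short for filter order", call. = FALSE)
  base <- x[1] + (x[n] - x[1]) * (0:(n - 1)) / (n - 1)
  z <- x - base
  np <- min(n - 1, max(3 * order, ceiling(5 * fs / cutoff_hz)))
  left <- 2 * z[1] - z[(np + 1):2]
  right <- 2 * z[n] - z[(n - 1):(n - np)]
  zp <- c(left, z, right)
  bt <- signal::butter(order, cutoff_hz / (fs / 2))
  y <- as.numeric(signal::filter(bt, zp))
  y <- rev(as.numeric(signal::filter(bt, rev(y))))
  y[(np + 1):(np + n)] + base
}

#' Resample a conductance series
#'
#' Changes the sampling rate from `fs_in` to `fs_out`. When downsampling, an
#' anti-alias zero-phase Butterworth low-pass (order 8, cutoff
#' `0.4 * fs_out`) is applied first; the passband therefore preserves all
#' content below `0.4 * fs_out`, in particular the 0.4-4 Hz band consumed by
#' the spectral quality metric at the 8 Hz working rate. Sample values are
#' then interpolated onto the new uniform grid.
#'
#' @param x Numeric series.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Series of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (!all(is.finite(x))) stop("validation error: non-finite samples", call. = FALSE)
  stopifnot(fs_in > 0, fs_out > 0)
  if (length(x) < 8) stop("validation error: need at least 8 samples", call. = FALSE)
  if (fs_in == fs_out) return(x)
  n <- length(x)
  m <- round(n * fs_out / fs_in)
  t_in <- (0:(n - 1)) / fs_in
  t_out <- (0:(m - 1)) / fs_out
  if (fs_out < fs_in) {
    xf <- lowpass_filter(x, fs_in, order = 8, cutoff_hz = 0.4 * fs_out)
    stats::approx(t_in, xf, xout = t_out, rule = 2)$y
  } else {
    stats::spline(t_in, x, xout = t_out)$y
  }
}

#' Resample, filter and segment a recording by protocol stage
#'
#' Every site channel is resampled to `cfg$target_fs`. Two versions are kept:
#' the resampled-unfiltered signal (consumed by the spectral quality module,
#' whose noise band lies above the low-pass cutoff) and the low-pass filtered
#' signal (consumed by the decomposition/index path). Both are cut into
#' per-stage segments on the half-open interval `[start_s, end_s)`: the
#' sample at a shared boundary belongs to the later stage.
#'
#' @param rec An [eda_recording()].
#' @param annotations Annotation table from [stage_annotations()] or
#'   [read_annotations()]; all intervals must lie within the recording.
#' @param cfg An [pipeline_config()].
#' @return An object of class `eda_segments`: list with `subject_id`, `fs`,
#'   `sites`, `stages`, and `filtered` / `raw` lists mapping stage label to a
#'   samples-by-sites matrix.
#' @export
segment_by_stages <- function(rec, annotations, cfg = pipeline_config()) {
  validate_recording(rec, allow_negative = TRUE)
  fs <- cfg$target_fs
  dur <- recording_duration(rec)
  over <- annotations$end_s - rec$t0 > dur + 1e-9
  if (any(over))
    stop("range error: annotation outside recording for stage(s): ",
         paste(annotations$stage[over], collapse = ", "), call. = FALSE)

  raw_rs <- vapply(rec$sites, function(s) {
    resample_signal(rec$samples[, s], rec$fs, fs)
  }, numeric(round(nrow(rec$samples) * fs / rec$fs)))
  filt <- apply(raw_rs, 2, lowpass_filter, fs = fs,
                order = cfg$lowpass_order, cutoff_hz = cfg$lowpass_cutoff_hz)
  colnames(filt) <- colnames(raw_rs) <- rec$sites

  m <- nrow(raw_rs)
  cut_one <- function(mat, start_s, end_s) {
    k0 <- ceiling((start_s - rec$t0) * fs - 1e-9)    # 0-based first sample
    k1 <- ceiling((end_s - rec$t0) * fs - 1e-9) - 1  # 0-based last sample
    k0 <- max(0, k0); k1 <- min(m - 1, k1)
    mat[(k0 + 1):(k1 + 1), , drop = FALSE]
  }
  filtered <- raw <- list()
  for (i in seq_len(nrow(annotations))) {
    st <- annotations$stage[i]
    filtered[[st]] <- cut_one(filt, annotations$start_s[i], annotations$end_s[i])
    raw[[st]] <- cut_one(raw_rs, annotations$start_s[i], annotations$end_s[i])
  }
  structure(list(subject_id = rec$subject_id, fs = fs, sites = rec$sites,
                 stages = annotations$stage, filtered = filtered, raw = raw),
            class = "eda_segments")
}

#' @export
print.eda_segments <- function(x, ...) {
  cat(sprintf("<eda_segments> subject %s @ %g Hz\n", x$subject_id, x$fs))
  for (st in x$stages)
    cat(sprintf("  %-14s %d samples x %d sites\n", st,
                nrow(x$filtered[[st]]), ncol(x$filtered[[st]])))
  invisible(x)
}
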