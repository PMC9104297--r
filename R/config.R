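#' Analysis pipeline configuration
#'
#' Collects the constants that drive the preprocessing, index-extraction,
#' quality and statistical stages. Defaults follow the standard protocol for
#' multi-site EDA comparison: the working rate is 8 Hz (resampled from a
#' 100 Hz acquisition rate), the decomposition/index path is low-pass
#' filtered with a zero-phase order-6 Butterworth at 0.6 Hz (well above the
#' < 0.4 Hz band of autonomic EDA dynamics), skin conductance responses are
#' counted above 0.05 of the per-segment maximum phasic peak, spectral
#' quality uses a Welch periodogram with 50% overlap and a > 0.4 Hz noise
#' band, and hypothesis tests use the 0.05 significance level.
#'
#' @param target_fs Working sampling rate in Hz after resampling.
#' @param lowpass_order Butterworth low-pass filter order.
#' @param lowpass_cutoff_hz Low-pass cutoff frequency in Hz.
#' @param noise_band_low_hz Lower edge of the spectral noise band in Hz;
#'   power above this frequency is attributed to motion artifact or noise.
#' @param scr_threshold_fraction SCR detection threshold as a fraction of the
#'   maximum phasic peak amplitude of the analysed segment.
#' @param significance_level Two-sided significance level for stage
#'   comparisons.
#' @param correlation_cut Correlation cut used when counting subjects with
#'   "responsive" alternative sites (strictly greater than).
#' @param welch_overlap_fraction Fractional overlap of Welch windows.
#' @param welch_segment_s Welch window length in seconds.
#' @param reference_site Label of the reference channel for within-subject
#'   correlations (the finger, by field convention).
#'
#' @return A list of class `eda_pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$target_fs
pipeline_config <- function(target_fs = 8,
                            lowpass_order = 6,
                            lowpass_cutoff_hz = 0.6,
                            noise_band_low_hz = 0.4,
                            scr_threshold_fraction = 0.05,
                            significance_level = 0.05,
                            correlation_cut = 0.5,
                            welch_overlap_fraction = 0.5,
                            welch_segment_s = 32,
                            reference_site = "finger") {
  cfg <- list(target_fs = target_fs,
              lowpass_order = as.integer(lowpass_order),
              lowpass_cutoff_hz = lowpass_cutoff_hz,
              noise_band_low_hz = noise_band_low_hz,
              scr_threshold_fraction = scr_threshold_fraction,
              significance_level = significance_level,
              correlation_cut = correlation_cut,
              welch_overlap_fraction = welch_overlap_fraction,
              welch_segment_s = welch_segment_s,
              reference_site = reference_site)
  class(cfg) <- "eda_pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "eda_pipeline_config"))
  if (!(cfg$target_fs > 0)) stop("target_fs must be positive", call. = FALSE)
  if (!(cfg$lowpass_cutoff_hz > 0 && cfg$lowpass_cutoff_hz < cfg$target_fs / 2))
    stop("lowpass_cutoff_hz must lie in (0, target_fs/2)", call. = FALSE)
  if (!(cfg$noise_band_low_hz > 0))
    stop("noise_band_low_hz must be positive", call. = FALSE)
  if (!(cfg$scr_threshold_fraction > 0 && cfg$scr_threshold_fraction < 1))
    stop("scr_threshold_fraction must lie in (0, 1)", call. = FALSE)
  if (!(cfg$welch_overlap_fraction > 0 && cfg$welch_overlap_fraction < 1))
    stop("welch_overlap_fraction must lie in (0, 1)", call. = FALSE)
  if (!(cfg$significance_level > 0 && cfg$significance_level < 1))
    stop("significance_level must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read or write a pipeline configuration
#'
#' Configurations are stored as YAML or JSON with the field names of
#' [pipeline_config()]. The file extension selects the format.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return For `read_pipeline_config`, an `eda_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg An `eda_pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
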