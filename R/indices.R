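#' Detect skin conductance responses in a phasic trace
#'
#' Finds local maxima of the phasic series whose amplitude reaches
#' `threshold_fraction` of the maximum peak amplitude of the same series
#' (an adaptive, scale-free threshold: multiplying the trace by a positive
#' constant leaves the count unchanged). To suppress numerical jitter, a
#' counted peak must also *rise* by at least the threshold (topographic
#' prominence): a decaying SCR shoulder sits above the amplitude threshold
#' for tens of seconds, and without the prominence requirement any
#' infinitesimal ripple on it would be counted as a response. Peaks closer
#' than 1 s to a larger accepted peak are suppressed. A trace with no
#' positive values yields no SCRs.
#'
#' @param phasic Phasic conductance series in microsiemens.
#' @param fs Sampling rate in Hz.
#' @param threshold_fraction Fraction of the maximum peak amplitude, in
#'   `(0, 1)`.
#' @param min_separation_s Minimum separation between accepted peaks.
#' @return A data.frame with columns `peak_time_s` and `peak_amplitude_us`,
#'   ordered by time (zero rows if nothing is detected).
#' @export
#' @examples
#' t <- (0:799) / 8
#' x <- exp(-(t - 20)^2) + 0.5 * exp(-(t - 50)^2) + 0.03 * exp(-(t - 80)^2)
#' nrow(detect_scrs(x, fs = 8, threshold_fraction = 0.05)) # 2
detect_scrs <- function(phasic, fs, threshold_fraction = 0.05,
                        min_separation_s = 1) {
  if (!all(is.finite(phasic))) stop("validation error: non-finite phasic", call. = FALSE)
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop("validation error: threshold_fraction must lie in (0, 1)", call. = FALSE)
  empty <- data.frame(peak_time_s = numeric(0), peak_amplitude_us = numeric(0))
  n <- length(phasic)
  if (n < 3) return(empty)
  mx <- max(phasic)
  if (!(mx > 0)) return(empty)
  thr <- threshold_fraction * mx

  left <- phasic[2:(n - 1)] - phasic[1:(n - 2)]
  right <- phasic[2:(n - 1)] - phasic[3:n]
  is_peak <- which(left > 0 & right >= 0) + 1
  is_peak <- is_peak[phasic[is_peak] >= thr]
  if (length(is_peak) == 0) return(empty)

  # topographic prominence: drop to the lowest point before a higher sample
  # (or the series edge) on each side; keep peaks rising by >= the threshold
  prom <- vapply(is_peak, function(i) {
    pk <- phasic[i]
    lmin <- pk
    j <- i - 1
    while (j >= 1 && phasic[j] <= pk) { lmin <- min(lmin, phasic[j]); j <- j - 1 }
    rmin <- pk
    j <- i + 1
    while (j <= n && phasic[j] <= pk) { rmin <- min(rmin, phasic[j]); j <- j + 1 }
    pk - max(lmin, rmin)
  }, numeric(1))
  is_peak <- is_peak[prom >= thr]
  if (length(is_peak) == 0) return(empty)

  # greedy suppression: keep the largest peaks, drop neighbours within 1 s
  ord <- is_peak[order(phasic[is_peak], decreasing = TRUE)]
  min_gap <- min_separation_s * fs
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(peak_time_s = (kept - 1) / fs,
             peak_amplitude_us = phasic[kept])
}

#' Compute the per-segment EDA indices
#'
#' The five standard indices of one stage segment at one site: the number of
#' skin conductance responses (adaptive threshold, see [detect_scrs()]), the
#' mean and variance of the phasic signal, and the mean and variance of the
#' tonic signal (skin conductance level). Variances use the unbiased (n-1)
#' estimator.
#'
#' @param dec An `eda_decomposition` (must have converged).
#' @param fs Sampling rate in Hz.
#' @param cfg An [pipeline_config()]; supplies the SCR threshold fraction.
#' @param stage,site,subject_id Labels attached to the output row.
#' @return A one-row data.frame with columns `subject_id`, `site`, `stage`,
#'   `n_scr`, `phasic_mean`, `phasic_variance`, `tonic_mean`,
#'   `tonic_variance`.
#' @export
compute_indices <- function(dec, fs = dec$fs, cfg = pipeline_config(),
                            stage = NA_character_, site = NA_character_,
                            subject_id = NA_character_) {
  if (!inherits(dec, "eda_decomposition"))
    stop("dec must be an eda_decomposition", call. = FALSE)
  if (!isTRUE(dec$converged))
    stop("refused: decomposition did not converge (", dec$iterations,
         " iterations, objective ", format(dec$objective_value), ")",
         call. = FALSE)
  scrs <- detect_scrs(dec$phasic, fs, cfg$scr_threshold_fraction)
  data.frame(subject_id = subject_id, site = site, stage = stage,
             n_scr = nrow(scrs),
             phasic_mean = mean(dec$phasic),
             phasic_variance = stats::var(dec$phasic),
             tonic_mean = mean(dec$tonic),
             tonic_variance = stats::var(dec$tonic),
             stringsAsFactors = FALSE)
}

#' Pivot an index table to tidy long format
#'
#' @param indices A data.frame of index rows from [compute_indices()].
#' @return A tidy data.frame with columns `subject_id`, `site`, `stage`,
#'   `index`, `value`.
#' @export
indices_long <- function(indices) {
  idx_cols <- c("n_scr", "phasic_mean", "phasic_variance",
                "tonic_mean", "tonic_variance")
  out <- do.call(rbind, lapply(idx_cols, function(cn) {
    data.frame(subject_id = indices$subject_id, site = indices$site,
               stage = indices$stage, index = cn, value = indices[[cn]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
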