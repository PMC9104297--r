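#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann taper. Each window is linearly
#' detrended before tapering, so the estimate describes fluctuation power
#' and is insensitive to the (large) conductance mean and slow trend. The
#' density is one-sided and normalised so that the integral over frequency
#' approximates the series variance.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param segment_s Window length in seconds.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `(0, 1)`.
#' @return A list with `freq` (Hz, from 0 to `fs/2`), `psd` (power density),
#'   `n_windows`, `nseg`.
#' @export
#' @examples
#' t <- (0:959) / 8
#' w <- welch_psd(sin(2 * pi * 0.5 * t), fs = 8)
#' sum(w$psd) * w$freq[2]  # close to 0.5 = A^2/2
welch_psd <- function(x, fs, segment_s = 32, overlap_fraction = 0.5) {
  if (!all(is.finite(x))) stop("validation error: non-finite samples", call. = FALSE)
  if (!(overlap_fraction > 0 && overlap_fraction < 1))
    stop("validation error: overlap_fraction must lie in (0, 1)", call. = FALSE)
  nseg <- round(segment_s * fs)
  n <- length(x)
  if (nseg > n)
    stop("validation error: Welch window longer than the data", call. = FALSE)
  if (nseg < 8) stop("validation error: Welch window too short", call. = FALSE)
  step <- max(1, round(nseg * (1 - overlap_fraction)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / nseg))  # periodic Hann
  U <- sum(w^2)
  k <- 0:(nseg - 1)
  kc <- k - mean(k)
  sxx <- sum(kc^2)
  half <- floor(nseg / 2)
  acc <- numeric(half + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    slope <- sum(kc * seg) / sxx
    segd <- seg - mean(seg) - slope * kc
    X <- stats::fft(w * segd)
    P <- (Mod(X[1:(half + 1)])^2) / (fs * U)
    P[2:half] <- 2 * P[2:half]   # one-sided (DC and Nyquist not doubled)
    acc <- acc + P
  }
  list(freq = (0:half) * fs / nseg,
       psd = acc / length(starts),
       n_windows = length(starts),
       nseg = nseg)
}

#' Noise-band power fraction (signal quality metric)
#'
#' The fraction `Pn` of total spectral power that lies in the noise band
#' (frequencies above `cfg$noise_band_low_hz`, by default 0.4 Hz, up to the
#' Nyquist rate). Autonomic EDA dynamics live below 0.4 Hz, so power above
#' that edge is attributed to motion artifact or noise: the higher `Pn`,
#' the more artifact-contaminated the segment. `Pn` should be computed on
#' the resampled-unfiltered signal; after the 0.6 Hz low-pass the noise band
#' is empty by construction.
#'
#' @param x Numeric series (resampled, unfiltered conductance).
#' @param fs Sampling rate in Hz; must exceed twice the band edge.
#' @param cfg An [pipeline_config()]; supplies the band edge and Welch
#'   parameters.
#' @param stage,site,subject_id Optional labels attached to the report.
#' @return A list of class `eda_quality` with `pn` (in `[0, 1]`, `NA` when
#'   degenerate), `total_power`, `noise_band_power`, `degenerate`, `freq`,
#'   `psd` and the labels.
#' @export
#' @examples
#' t <- (0:959) / 8
#' noise_power_fraction(sin(2 * pi * 1 * t), fs = 8)$pn  # close to 1
noise_power_fraction <- function(x, fs, cfg = pipeline_config(),
                                 stage = NA_character_, site = NA_character_,
                                 subject_id = NA_character_) {
  if (!(fs > 2 * cfg$noise_band_low_hz))
    stop("validation error: fs must exceed twice the noise band edge",
         call. = FALSE)
  w <- welch_psd(x, fs, segment_s = min(cfg$welch_segment_s, length(x) / fs),
                 overlap_fraction = cfg$welch_overlap_fraction)
  df <- w$freq[2] - w$freq[1]
  pos <- w$freq > 0
  band <- w$freq > cfg$noise_band_low_hz
  total <- sum(w$psd[pos]) * df
  noise <- sum(w$psd[band]) * df
  degenerate <- !(total > 1e-14 * max(1, mean(x)^2))
  structure(list(pn = if (degenerate) NA_real_ else noise / total,
                 total_power = total, noise_band_power = noise,
                 degenerate = degenerate,
                 freq = w$freq, psd = w$psd, n_windows = w$n_windows,
                 stage = stage, site = site, subject_id = subject_id),
            class = "eda_quality")
}

#' @export
print.eda_quality <- function(x, ...) {
  cat(sprintf("<eda_quality> Pn = %s (total power %.4g uS^2, %d windows)\n",
              if (x$degenerate) "degenerate" else sprintf("%.4f", x$pn),
              x$total_power, x$n_windows))
  invisible(x)
}
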