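#' Site response profile for the EDA simulator
#'
#' Describes how one body site transduces central sudomotor activity into
#' skin conductance, and which motion artifacts it is exposed to. Sites
#' differ in eccrine gland density and innervation, so the same central
#' burst may or may not elicit a skin conductance response (SCR) at a given
#' site; `responsiveness` is the per-event probability that it does. Sites
#' also show site-local, stimulus-independent SCRs (e.g. thermoregulatory
#' activity on the forehead), controlled by `spontaneous_scr_rate_per_min`.
#'
#' @param label Site label.
#' @param gain Unitless multiplier applied to SCR amplitudes at this site.
#' @param tonic_level_us Mean tonic skin conductance level in microsiemens.
#' @param tonic_drift_sd Standard deviation of the smoothed random-walk
#'   tonic drift, in microsiemens per sqrt(second).
#' @param responsiveness Probability in `[0, 1]` that a central sudomotor
#'   event elicits an SCR at this site.
#' @param responsiveness_subject_sd Between-subject SD of the responsiveness
#'   (per-subject value drawn once, clamped to `[0, 1]`). When a hydration
#'   ramp is active the heterogeneity applies to the end-of-session value
#'   (how far each subject hydrates), otherwise to the constant value.
#' @param responsiveness_end If non-`NA`, the responsiveness ramps from
#'   `responsiveness` at the start of the recording to this value at the end
#'   following a lag-phase (quadratic in time) profile: skin hydration needs
#'   tens of minutes, so within a short session the early stages see almost
#'   no stimulus coupling and the rise concentrates late in the session.
#' @param spontaneous_scr_rate_per_min Rate of site-local SCRs that are not
#'   driven by the central (stress-modulated) process.
#' @param walking_noise_sd SD in microsiemens of band-limited (0.4-4 Hz)
#'   artifact noise added during the walking stage.
#' @param lift_artifact_rate Expected electrode-motion transients per minute
#'   during the weightlifting stage.
#' @param lift_artifact_amp_us Typical amplitude of those transients, in
#'   microsiemens.
#'
#' @return A list of class `eda_site_profile`.
#' @export
site_profile <- function(label,
                         gain = 1,
                         tonic_level_us = 5,
                         tonic_drift_sd = 0.01,
                         responsiveness = 0.9,
                         responsiveness_subject_sd = 0,
                         responsiveness_end = NA_real_,
                         spontaneous_scr_rate_per_min = 0,
                         walking_noise_sd = 0,
                         lift_artifact_rate = 0,
                         lift_artifact_amp_us = 0) {
  stopifnot(gain > 0,
            responsiveness >= 0, responsiveness <= 1,
            tonic_drift_sd >= 0, walking_noise_sd >= 0,
            lift_artifact_rate >= 0, lift_artifact_amp_us >= 0,
            spontaneous_scr_rate_per_min >= 0,
            responsiveness_subject_sd >= 0)
  structure(list(label = label, gain = gain,
                 tonic_level_us = tonic_level_us,
                 tonic_drift_sd = tonic_drift_sd,
                 responsiveness = responsiveness,
                 responsiveness_subject_sd = responsiveness_subject_sd,
                 responsiveness_end = responsiveness_end,
                 spontaneous_scr_rate_per_min = spontaneous_scr_rate_per_min,
                 walking_noise_sd = walking_noise_sd,
                 lift_artifact_rate = lift_artifact_rate,
                 lift_artifact_amp_us = lift_artifact_amp_us),
            class = "eda_site_profile")
}

#' Default site profiles for the four-site study conditions
#'
#' Finger (reference) and foot are strongly coupled to central sudomotor
#' activity from the start (palmar/plantar sites need no hydration time).
#' Forehead and neck start the session barely responsive and hydrate slowly:
#' their responsiveness ramps from near zero towards a moderate value over
#' the session, so during the early (baseline and cognitive-stress) stages
#' their phasic activity is dominated by stimulus-independent spontaneous
#' SCRs and shows large between-subject variability. The foot picks up
#' gait-band noise while walking; the finger and, above all, the neck are
#' distorted by electrode motion during one-handed weightlifting. Tonic
#' levels follow the typical per-site skin conductance ranges (forehead much
#' higher than the distal sites).
#'
#' @return A list of four [site_profile()] objects named by site.
#' @export
default_site_profiles <- function() {
  list(
    forehead = site_profile("forehead", gain = 0.6, tonic_level_us = 25,
                            tonic_drift_sd = 0.03,
                            responsiveness = 0,
                            responsiveness_subject_sd = 0.1,
                            responsiveness_end = 0.3,
                            spontaneous_scr_rate_per_min = 5,
                            walking_noise_sd = 0.01,
                            lift_artifact_rate = 0.5,
                            lift_artifact_amp_us = 0.3),
    neck = site_profile("neck", gain = 0.4, tonic_level_us = 4.2,
                        tonic_drift_sd = 0.02,
                        responsiveness = 0,
                        responsiveness_subject_sd = 0.1,
                        responsiveness_end = 0.25,
                        spontaneous_scr_rate_per_min = 2,
                        walking_noise_sd = 0.03,
                        lift_artifact_rate = 6,
                        lift_artifact_amp_us = 1),
    finger = site_profile("finger", gain = 1, tonic_level_us = 6.5,
                          tonic_drift_sd = 0.01,
                          responsiveness = 0.9,
                          responsiveness_subject_sd = 0.05,
                          spontaneous_scr_rate_per_min = 0.5,
                          walking_noise_sd = 0.02,
                          lift_artifact_rate = 8,
                          lift_artifact_amp_us = 2),
    foot = site_profile("foot", gain = 0.8, tonic_level_us = 5.5,
                        tonic_drift_sd = 0.01,
                        responsiveness = 0.85,
                        responsiveness_subject_sd = 0.05,
                        spontaneous_scr_rate_per_min = 0.5,
                        walking_noise_sd = 0.2,
                        lift_artifact_rate = 0.5,
                        lift_artifact_amp_us = 0.5)
  )
}

#' Simulation configuration
#'
#' Parameters of the generative model mirrored by the decomposition: skin
#' conductance is the sum of a tonic level with slow drift, a phasic
#' component (sparse sudomotor events convolved with a unit-peak
#' biexponential kernel), stage-specific motion artifacts, and white
#' Gaussian measurement noise. Central sudomotor events follow a homogeneous
#' Poisson process whose rate is multiplied by `scr_rate_stress_multiplier`
#' during the cognitive-stress (scwt) stage.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param stage_plan Stage plan (`stage`, `duration_s`); defaults to the
#'   four-stage 120 s protocol of [default_stage_plan()].
#' @param fs_raw Acquisition sampling rate in Hz.
#' @param scr_rate_baseline_per_min Central sudomotor event rate at rest.
#' @param scr_rate_stress_multiplier Rate multiplier during the scwt stage
#'   (must exceed 1).
#' @param scr_amplitude_mean_us,scr_amplitude_sd_us Mean and SD of SCR
#'   amplitudes (microsiemens) before site gain; drawn from a normal
#'   distribution truncated at zero.
#' @param kernel_tau_rise_s,kernel_tau_decay_s Rise and decay time constants
#'   of the biexponential SCR kernel, in seconds.
#' @param measurement_noise_sd_us SD of the additive white measurement noise.
#' @param tonic_level_subject_cv Between-subject coefficient of variation of
#'   the tonic level (log-normal).
#' @param site_profiles List of [site_profile()] objects.
#' @param seed Integer master seed; every random draw derives from it.
#'
#' @return A list of class `eda_simulation_config`.
#' @export
simulation_config <- function(n_subjects = 23,
                              stage_plan = default_stage_plan(),
                              fs_raw = 100,
                              scr_rate_baseline_per_min = 3,
                              scr_rate_stress_multiplier = 2,
                              scr_amplitude_mean_us = 0.4,
                              scr_amplitude_sd_us = 0.2,
                              kernel_tau_rise_s = 0.7,
                              kernel_tau_decay_s = 2.0,
                              measurement_noise_sd_us = 0.01,
                              tonic_level_subject_cv = 0.2,
                              site_profiles = default_site_profiles(),
                              seed = 1L) {
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        stage_plan = stage_plan,
                        fs_raw = fs_raw,
                        scr_rate_baseline_per_min = scr_rate_baseline_per_min,
                        scr_rate_stress_multiplier = scr_rate_stress_multiplier,
                        scr_amplitude_mean_us = scr_amplitude_mean_us,
                        scr_amplitude_sd_us = scr_amplitude_sd_us,
                        kernel_tau_rise_s = kernel_tau_rise_s,
                        kernel_tau_decay_s = kernel_tau_decay_s,
                        measurement_noise_sd_us = measurement_noise_sd_us,
                        tonic_level_subject_cv = tonic_level_subject_cv,
                        site_profiles = site_profiles,
                        seed = as.integer(seed)),
                   class = "eda_simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "eda_simulation_config"))
  if (is.null(cfg$stage_plan) || nrow(cfg$stage_plan) == 0)
    stop("validation error: stage plan is empty", call. = FALSE)
  if (!all(cfg$stage_plan$duration_s > 0))
    stop("stage durations must be positive", call. = FALSE)
  if (!(cfg$scr_rate_baseline_per_min > 0))
    stop("scr_rate_baseline_per_min must be positive", call. = FALSE)
  if (!(cfg$scr_rate_stress_multiplier > 1))
    stop("scr_rate_stress_multiplier must exceed 1", call. = FALSE)
  if (!(cfg$kernel_tau_rise_s < cfg$kernel_tau_decay_s))
    stop("kernel_tau_rise_s must be smaller than kernel_tau_decay_s",
         call. = FALSE)
  if (!(cfg$fs_raw > 0)) stop("fs_raw must be positive", call. = FALSE)
  if (length(cfg$site_profiles) < 1)
    stop("at least one site profile is required", call. = FALSE)
  invisible(cfg)
}

# Deterministic per-subject seed stream derived from the master seed.
# subject_index is 0-based so simulate_recording(cfg, 0) is subject one.
subject_seed <- function(master_seed, subject_index) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(master_seed)
  draws <- sample.int(2147483646L, subject_index + 1L)
  draws[subject_index + 1L]
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Normal(mean, sd) truncated at zero, by rejection (vectorised).
rnorm_trunc0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
    guard <- guard + 1
  }
  out[out < 0] <- 0
  out
}

# Unit-peak biexponential kernel evaluated at times tau >= 0.
biexp_unit_peak <- function(tau, tau_rise, tau_decay) {
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  val <- exp(-tau / tau_decay) - exp(-tau / tau_rise)
  val[tau < 0] <- 0
  val / pk
}

# Smooth tonic drift: a random walk sampled at 1 Hz knots, spline-interpolated
# onto the sample grid. Var(drift(t)) = tonic_drift_sd^2 * t at the knots.
tonic_drift <- function(t, drift_sd) {
  if (drift_sd <= 0) return(numeric(length(t)))
  tmax <- max(t)
  knots <- 0:ceiling(tmax + 1)
  walk <- c(0, cumsum(stats::rnorm(length(knots) - 1, 0, drift_sd)))
  stats::spline(knots, walk, xout = t)$y
}

# Band-limited (0.4-4 Hz) gait noise with the requested SD over its support.
walking_noise <- function(n, fs, sd_target) {
  if (sd_target <= 0 || n < 32) return(numeric(n))
  pad <- round(4 * fs)
  z <- stats::rnorm(n + 2 * pad)
  hi <- min(4, 0.45 * fs)
  bp <- signal::butter(2, c(0.4, hi) / (fs / 2), type = "pass")
  zf <- as.numeric(signal::filter(bp, z))
  zf <- zf[(pad + 1):(pad + n)]
  zf * sd_target / stats::sd(zf)
}

# Electrode-motion transient: ~1 s pulse with raised-cosine edges.
lift_pulse <- function(dur_samples) {
  k <- seq_len(dur_samples)
  edge <- max(2, round(0.2 * dur_samples))
  w <- rep(1, dur_samples)
  up <- seq_len(edge)
  w[up] <- 0.5 * (1 - cos(pi * up / edge))
  w[dur_samples - edge + up] <- rev(w[up])
  w
}

#' Simulate one multi-site EDA recording with ground truth
#'
#' Draws central sudomotor events as a Poisson process (rate elevated during
#' the scwt stage), thins them per site by responsiveness, adds site-local
#' spontaneous events, convolves all events with the unit-peak biexponential
#' kernel, and adds tonic level plus smoothed random-walk drift,
#' stage-specific motion artifacts (gait-band noise while walking,
#' electrode-motion transients while weightlifting) and white measurement
#' noise. The emitted samples equal
#' `tonic + phasic + artifact + measurement noise` exactly; the first three
#' are returned as ground-truth traces, so the residual recovers the noise
#' realisation.
#'
#' @param cfg An [simulation_config()].
#' @param subject_index 0-based subject index; selects a deterministic
#'   per-subject seed stream from `cfg$seed`.
#' @return A list with elements `recording` (an [eda_recording()]) and
#'   `truth` (class `eda_ground_truth`): per site, the event times and
#'   amplitudes plus tonic, phasic and artifact traces, and the seed used.
#' @export
#' @examples
#' sim <- simulate_recording(simulation_config(seed = 7), 0)
#' sim$recording
#' length(sim$truth$sites$finger$event_times_s)
simulate_recording <- function(cfg, subject_index = 0) {
  validate_simulation_config(cfg)
  seed_i <- subject_seed(cfg$seed, subject_index)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed_i)

  fs <- cfg$fs_raw
  plan <- cfg$stage_plan
  total_s <- sum(plan$duration_s)
  n <- round(total_s * fs)
  t <- (0:(n - 1)) / fs
  stage_end <- cumsum(plan$duration_s)
  stage_start <- c(0, stage_end[-length(stage_end)])
  scwt_row <- which(plan$stage == "scwt")

  # central events: homogeneous process at the maximal rate, thinned to the
  # stage-dependent rate profile
  base_rate <- cfg$scr_rate_baseline_per_min / 60
  mult <- cfg$scr_rate_stress_multiplier
  rate_max <- base_rate * mult
  n_cand <- stats::rpois(1, rate_max * total_s)
  cand <- sort(stats::runif(n_cand, 0, total_s))
  in_scwt <- if (length(scwt_row) == 1) {
    cand >= stage_start[scwt_row] & cand < stage_end[scwt_row]
  } else rep(FALSE, n_cand)
  accept_p <- ifelse(in_scwt, 1, 1 / mult)
  central <- cand[stats::runif(n_cand) < accept_p]

  kernel_support <- -cfg$kernel_tau_decay_s * log(1e-7)

  sites <- list()
  cols <- list()
  for (sp in cfg$site_profiles) {
    resp0 <- sp$responsiveness
    has_ramp <- !is.na(sp$responsiveness_end)
    resp1 <- if (has_ramp) sp$responsiveness_end else resp0
    if (sp$responsiveness_subject_sd > 0) {
      jit <- stats::rnorm(1, 0, sp$responsiveness_subject_sd)
      if (has_ramp) resp1 <- min(1, max(0, resp1 + jit))
      else resp0 <- resp1 <- min(1, max(0, resp0 + jit))
    }
    resp_at <- function(tt) resp0 + (resp1 - resp0) * (tt / total_s)^2

    keep <- stats::runif(length(central)) < resp_at(central)
    ev <- central[keep]
    n_spont <- stats::rpois(1, sp$spontaneous_scr_rate_per_min / 60 * total_s)
    ev <- sort(c(ev, stats::runif(n_spont, 0, total_s)))
    amp <- sp$gain * rnorm_trunc0(length(ev), cfg$scr_amplitude_mean_us,
                                  cfg$scr_amplitude_sd_us)

    phasic <- numeric(n)
    for (j in seq_along(ev)) {
      i0 <- floor(ev[j] * fs) + 1
      i1 <- min(n, ceiling((ev[j] + kernel_support) * fs))
      if (i0 > n) next
      idx <- i0:i1
      phasic[idx] <- phasic[idx] +
        amp[j] * biexp_unit_peak(t[idx] - ev[j], cfg$kernel_tau_rise_s,
                                 cfg$kernel_tau_decay_s)
    }

    level <- sp$tonic_level_us
    if (cfg$tonic_level_subject_cv > 0)
      level <- level * exp(stats::rnorm(1, 0, cfg$tonic_level_subject_cv))
    tonic <- level + tonic_drift(t, sp$tonic_drift_sd)

    artifact <- numeric(n)
    walk_row <- which(plan$stage == "walking")
    if (length(walk_row) == 1 && sp$walking_noise_sd > 0) {
      i0 <- floor(stage_start[walk_row] * fs) + 1
      i1 <- min(n, round(stage_end[walk_row] * fs))
      artifact[i0:i1] <- walking_noise(i1 - i0 + 1, fs, sp$walking_noise_sd)
    }
    lift_row <- which(plan$stage == "weightlifting")
    if (length(lift_row) == 1 && sp$lift_artifact_rate > 0) {
      dur <- plan$duration_s[lift_row]
      n_art <- stats::rpois(1, sp$lift_artifact_rate / 60 * dur)
      if (n_art > 0) {
        centers <- stats::runif(n_art, stage_start[lift_row], stage_end[lift_row])
        for (ctr in centers) {
          len_s <- stats::runif(1, 0.7, 1.3)
          sgn <- sample(c(-1, 1), 1)
          a <- sp$lift_artifact_amp_us * stats::runif(1, 0.7, 1.3)
          i0 <- max(1, floor((ctr - len_s / 2) * fs) + 1)
          i1 <- min(n, i0 + round(len_s * fs) - 1)
          if (i1 > i0)
            artifact[i0:i1] <- artifact[i0:i1] + sgn * a * lift_pulse(i1 - i0 + 1)
        }
      }
    }

    noise <- stats::rnorm(n, 0, cfg$measurement_noise_sd_us)
    cols[[sp$label]] <- tonic + phasic + artifact + noise
    sites[[sp$label]] <- list(event_times_s = ev,
                              event_amplitudes_us = amp,
                              tonic_trace = tonic,
                              phasic_trace = phasic,
                              artifact_trace = artifact)
  }

  samples <- do.call(cbind, cols)
  rec <- eda_recording(samples, fs = fs, sites = names(cols),
                       subject_id = sprintf("s%02d", subject_index + 1),
                       allow_negative = TRUE)
  truth <- structure(list(subject_index = subject_index, seed = seed_i,
                          sites = sites, stage_plan = plan),
                     class = "eda_ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate a cohort of subjects
#'
#' @param cfg An [simulation_config()]; `cfg$n_subjects` independent subjects
#'   are generated with per-subject seeds derived deterministically from
#'   `cfg$seed`.
#' @return A list of `cfg$n_subjects` elements, each as returned by
#'   [simulate_recording()].
#' @export
simulate_cohort <- function(cfg) {
  validate_simulation_config(cfg)
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  lapply(seq_len(cfg$n_subjects) - 1L, function(i) simulate_recording(cfg, i))
}

#' Count ground-truth events inside a stage
#'
#' @param truth An `eda_ground_truth` from [simulate_recording()].
#' @param site Site label.
#' @param stage Stage label (must be present in the stage plan).
#' @return Number of ground-truth SCR events of `site` within the stage
#'   interval (half-open).
#' @export
truth_event_count <- function(truth, site, stage) {
  plan <- truth$stage_plan
  row <- which(plan$stage == stage)
  if (length(row) != 1) stop("stage not in plan: ", stage, call. = FALSE)
  ends <- cumsum(plan$duration_s)
  starts <- c(0, ends[-length(ends)])
  ev <- truth$sites[[site]]$event_times_s
  sum(ev >= starts[row] & ev < ends[row])
}
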