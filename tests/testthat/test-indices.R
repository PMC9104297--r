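test_that("SCR threshold rule reproduces the forced three-bump example", {
  fs <- 8
  ph <- clean_phasic(120, fs, c(20, 50, 80), c(1.0, 0.5, 0.03))
  pk <- detect_scrs(ph, fs, threshold_fraction = 0.05)
  expect_equal(nrow(pk), 2) # threshold 0.05 * 1.0 = 0.05 > 0.03
  expect_true(all(abs(sort(pk$peak_time_s) - (c(20, 50) + 1.13)) < 0.5))
})

test_that("degenerate phasic input yields zero SCRs", {
  expect_equal(nrow(detect_scrs(numeric(960), 8)), 0)
  expect_equal(nrow(detect_scrs(rep(-0.2, 960), 8)), 0)
})

test_that("SCR count is invariant to positive rescaling", {
  set.seed(6)
  ph <- clean_phasic(120, 8, sort(runif(8, 5, 110)), runif(8, 0.1, 1)) +
    abs(rnorm(960, 0, 0.002))
  n0 <- nrow(detect_scrs(ph, 8))
  scales <- exp(runif(100, -4, 4))
  for (c in scales) expect_equal(nrow(detect_scrs(c * ph, 8)), n0)
})

test_that("adding one SCR above threshold increases the count by one", {
  set.seed(7)
  for (i in 1:5) {
    onsets <- sort(sample(seq(10, 100, by = 8), 5))
    ph <- clean_phasic(120, 8, onsets, runif(5, 0.4, 0.9))
    n0 <- nrow(detect_scrs(ph, 8))
    ph2 <- ph + biexp_bump((0:959) / 8, 110, 0.6)
    expect_equal(nrow(detect_scrs(ph2, 8)), n0 + 1)
  }
})

test_that("clean simulated SCRs are counted exactly with matched times", {
  # 10 well-separated events, amplitudes >= 0.3, no noise
  fs <- 8
  onsets <- seq(8, 107, by = 11)
  amps <- seq(0.3, 0.75, length.out = 10)
  ph <- clean_phasic(120, fs, onsets, amps)
  d <- decompose(5 + ph, fs)
  pk <- detect_scrs(d$phasic, fs, 0.05)
  expect_equal(nrow(pk), 10)
  peak_t <- onsets + 1.13
  expect_true(all(vapply(peak_t,
                         function(o) min(abs(pk$peak_time_s - o)) <= 1,
                         logical(1))))
})

test_that("index values match hand computation", {
  dec <- structure(list(tonic = c(4, 5, 6), phasic = c(0, 0, 0),
                        converged = TRUE, fs = 8),
                   class = "eda_decomposition")
  idx <- compute_indices(dec, fs = 8, stage = "baseline", site = "finger",
                         subject_id = "s01")
  expect_equal(idx$tonic_mean, 5)
  expect_equal(idx$tonic_variance, 1.0) # unbiased: ((-1)^2 + 0 + 1^2) / 2
  expect_equal(idx$n_scr, 0)
  expect_equal(idx$phasic_mean, 0)
  expect_equal(idx$phasic_variance, 0)

  dec$converged <- FALSE
  dec$iterations <- 10L
  dec$objective_value <- 1
  expect_error(compute_indices(dec, fs = 8), "refused")
})

test_that("stress stage raises the detected SCR count across replicates", {
  # two-stage plan; full decomposition + detection path per replicate
  # moderate rate and long stages keep SCRs well separated, so the detector
  # tracks the underlying Poisson counts
  plan <- data.frame(stage = c("baseline", "scwt"), duration_s = c(360, 360))
  ann <- annotations_from_plan(plan)
  pos <- vapply(1:100, function(i) {
    cfg <- simulation_config(
      n_subjects = 1, stage_plan = plan, fs_raw = 25,
      scr_rate_baseline_per_min = 2,
      site_profiles = list(site_profile("finger", tonic_drift_sd = 0)),
      measurement_noise_sd_us = 0, tonic_level_subject_cv = 0,
      seed = 400 + i)
    sim <- simulate_recording(cfg, 0)
    seg <- segment_by_stages(sim$recording, ann)
    ns <- vapply(c("baseline", "scwt"), function(st) {
      d <- decompose(seg$filtered[[st]][, 1], 8)
      nrow(detect_scrs(d$phasic, 8, 0.05))
    }, numeric(1))
    ns["scwt"] - ns["baseline"]
  }, numeric(1))
  expect_gt(mean(pos), 0)
  expect_gte(mean(pos > 0), 0.95)
})

test_that("index tables pivot to tidy long format", {
  tab <- data.frame(subject_id = "s01", site = "foot", stage = "scwt",
                    n_scr = 4, phasic_mean = 0.2, phasic_variance = 0.01,
                    tonic_mean = 5, tonic_variance = 0.1)
  long <- indices_long(tab)
  expect_equal(nrow(long), 5)
  expect_setequal(long$index, c("n_scr", "phasic_mean", "phasic_variance",
                                "tonic_mean", "tonic_variance"))
})
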