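test_that("resampling preserves DC and length contract", {
  y <- resample_signal(rep(5, 1200), 100, 8)
  expect_length(y, 96)
  interior <- y[9:88]
  expect_lt(max(abs(interior - 5)), 1e-6)
})

test_that("resampling preserves sub-cutoff sinusoid amplitude", {
  t_in <- (0:11999) / 100
  x <- sin(2 * pi * 0.2 * t_in)
  y <- resample_signal(x, 100, 8)
  t_out <- (0:(length(y) - 1)) / 8
  ref <- sin(2 * pi * 0.2 * t_out)
  interior <- 33:(length(y) - 32) # skip 4 s edges
  expect_lt(max(abs(y[interior] - ref[interior])), 0.02)
})

test_that("zero-phase Butterworth has unit DC gain and analytic attenuation", {
  y <- lowpass_filter(rep(5, 400), fs = 8, order = 6, cutoff_hz = 0.6)
  expect_lt(max(abs(y[17:384] - 5)), 1e-6)

  # 1 Hz tone: the analog prototype magnitude 1/sqrt(1+(1/0.6)^12) (squared
  # for zero-phase) bounds the digital filter, whose bilinear design
  # attenuates faster above cutoff; measure in steady state (25-35 s)
  t <- (0:(8 * 60 - 1)) / 8
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, 8, 6, 0.6)
  gain1 <- max(abs(y1[201:280]))
  analytic <- (1 / sqrt(1 + (1 / 0.6)^12))^2
  expect_lte(gain1, 1.1 * analytic)
  expect_gte(gain1, 0.2 * analytic)

  # 0.05 Hz tone passes essentially unchanged
  t2 <- (0:(8 * 120 - 1)) / 8
  x2 <- sin(2 * pi * 0.05 * t2)
  y2 <- lowpass_filter(x2, 8, 6, 0.05 * 12) # cutoff 0.6
  interior <- 161:(length(y2) - 160)
  expect_equal(max(abs(y2[interior])), 1, tolerance = 0.02)

  expect_error(lowpass_filter(x1, 8, 6, 4.2), "fs/2")
})

test_that("filtering is linear", {
  set.seed(9)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  a <- 1.7; b <- -0.4
  lhs <- lowpass_filter(a * x + b * y, 8, 6, 0.6)
  rhs <- a * lowpass_filter(x, 8, 6, 0.6) + b * lowpass_filter(y, 8, 6, 0.6)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("resample-then-filter commutes with filter-then-resample in band", {
  set.seed(14)
  t <- (0:23999) / 100
  # band-limited (< 0.4 Hz) input
  x <- 5 + 0.5 * sin(2 * pi * 0.1 * t) + 0.3 * sin(2 * pi * 0.3 * t + 1)
  a <- lowpass_filter(resample_signal(x, 100, 8), 8, 6, 0.6)
  b <- resample_signal(lowpass_filter(x, 100, 6, 0.6), 100, 8)
  interior <- 41:(length(a) - 40)
  rms_diff <- sqrt(mean((a[interior] - b[interior])^2))
  rms_sig <- sqrt(mean((b[interior] - mean(b[interior]))^2))
  expect_lt(rms_diff / rms_sig, 0.05)
})

test_that("stage segmentation follows the half-open convention", {
  cfg <- pipeline_config()
  scfg <- clean_sim_config(responsiveness = 0)
  rec <- simulate_recording(simulation_config(
    seed = 1, n_subjects = 1, tonic_level_subject_cv = 0,
    measurement_noise_sd_us = 0,
    site_profiles = list(site_profile("finger", responsiveness = 0))), 0)$recording
  ann <- annotations_from_plan()
  seg <- segment_by_stages(rec, ann, cfg)
  for (st in ann$stage) expect_equal(nrow(seg$filtered[[st]]), 960)
  # segments tile the record with no duplicated sample
  total <- sum(vapply(seg$raw, nrow, numeric(1)))
  expect_equal(total, 3840)
  recon <- do.call(rbind, seg$raw)
  full <- vapply(rec$sites, function(s) resample_signal(rec$samples[, s], 100, 8),
                 numeric(3840))
  expect_equal(unname(recon), unname(full))
  # annotation beyond the recording is a range error naming the stage
  bad <- stage_annotations("late", 400, 500)
  expect_error(segment_by_stages(rec, bad, cfg), "range error.*late")
})

test_that("a boundary sample belongs to the later stage only", {
  rec <- eda_recording(cbind(s = seq(1, 2, length.out = 80)), fs = 8,
                       sites = "s")
  # work at the native rate so indexing is transparent
  cfg <- pipeline_config(target_fs = 8)
  ann <- stage_annotations(c("a", "b"), c(0, 5), c(5, 10))
  seg <- segment_by_stages(rec, ann, cfg)
  expect_equal(nrow(seg$raw[["a"]]), 40)
  expect_equal(nrow(seg$raw[["b"]]), 40)
  # sample at t = 5 s is the first sample of "b"
  expect_equal(seg$raw[["b"]][1, "s"], rec$samples[41, "s"])
})
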