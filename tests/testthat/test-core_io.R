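test_that("recording CSV round-trip preserves values and labels", {
  set.seed(11)
  rec <- eda_recording(cbind(finger = 5 + cumsum(rnorm(40, 0, 0.05)),
                             foot = 4 + cumsum(rnorm(40, 0, 0.05))),
                       fs = 8, subject_id = "s01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  expect_equal(length(readLines(path)), 41) # header + 40 rows
  back <- read_recording(path, fs = 8, site_columns = c("finger", "foot"))
  expect_identical(back$sites, rec$sites)
  expect_equal(back$samples, rec$samples, tolerance = 1e-7)
})

test_that("read_recording reorders columns and reports format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,finger,foot", "0,1.5,2.5", "0.125,1.6,2.6",
               "0.25,1.7,2.7"), path)
  rec <- read_recording(path, fs = 8, site_columns = c("foot", "finger"))
  expect_equal(rec$sites, c("foot", "finger"))
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$samples[, "foot"], c(2.5, 2.6, 2.7))
  expect_error(read_recording(path, fs = 8, site_columns = "wrist"),
               "missing column.*wrist")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,finger", "0,1.5", "0.125,oops"), bad)
  expect_error(read_recording(bad, fs = 8, site_columns = "finger"),
               "row 2")
})

test_that("recording invariants are enforced", {
  expect_error(eda_recording(cbind(a = c(1, 2), a = c(1, 2)), fs = 8,
                             sites = c("a", "a")), "unique")
  expect_error(eda_recording(cbind(a = c(1, NA)), fs = 8), "finite")
  expect_error(eda_recording(cbind(a = c(1, -1)), fs = 8), "negative")
  expect_no_error(eda_recording(cbind(a = c(1, -1)), fs = 8,
                                allow_negative = TRUE))
  expect_error(eda_recording(cbind(a = 1), fs = 8), "2 samples")
  expect_error(eda_recording(cbind(a = c(1, 2)), fs = -8), "positive")
})

test_that("annotations follow the four-stage protocol and validate intervals", {
  ann <- stage_annotations(c("baseline", "scwt", "walking", "weightlifting"),
                           c(0, 120, 240, 360), c(120, 240, 360, 480))
  expect_equal(nrow(ann), 4)
  expect_equal(ann$end_s - ann$start_s, rep(120, 4))
  expect_error(stage_annotations("a", 10, 10), "end_s <= start_s")
  # unordered input comes back sorted
  ann2 <- stage_annotations(c("b", "a"), c(120, 0), c(240, 120))
  expect_equal(ann2$stage, c("a", "b"))
  # file round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path)$stage, ann$stage)
})

test_that("annotation validation rejects every overlapping pair", {
  set.seed(42)
  for (i in 1:25) {
    starts <- sort(runif(5, 0, 100))
    lens <- runif(5, 1, 30)
    ends <- starts + lens
    overlapping <- any(starts[-1] < ends[-5] - 1e-9)
    if (overlapping) {
      expect_error(stage_annotations(letters[1:5], starts, ends), "overlap")
    } else {
      expect_no_error(stage_annotations(letters[1:5], starts, ends))
    }
  }
  # construction guarantees overlap
  expect_error(stage_annotations(c("a", "b"), c(0, 5), c(10, 15)), "overlap")
})

test_that("pipeline config validates and round-trips through YAML and JSON", {
  cfg <- pipeline_config()
  expect_equal(cfg$target_fs, 8)
  expect_equal(cfg$lowpass_cutoff_hz, 0.6)
  expect_equal(cfg$scr_threshold_fraction, 0.05)
  expect_error(pipeline_config(lowpass_cutoff_hz = 5), "target_fs/2")
  expect_error(pipeline_config(scr_threshold_fraction = 1.2), "0, 1")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_pipeline_config(cfg, path)
    back <- read_pipeline_config(path)
    expect_equal(unclass(back), unclass(cfg))
  }
})
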