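test_that("pearson_r matches hand-computed coefficients", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("normality gate passes Gaussian and rejects two-point samples", {
  set.seed(20)
  g <- normality_gate(rnorm(23))
  expect_true(g)
  expect_gte(attr(g, "p_value"), 0.05)
  g2 <- normality_gate(rep(c(0, 10), length.out = 23))
  expect_false(g2)
  g3 <- normality_gate(rep(4, 23))
  expect_false(g3)
  expect_true(attr(g3, "degenerate"))
})

test_that("stage comparison picks the gated test and detects strong effects", {
  set.seed(22)
  b <- rnorm(23, 6, 1); s <- rnorm(23, 12, 1)
  res <- compare_stages(b, s)
  expect_equal(res$stat_name, "paired_t")
  expect_true(res$significant)
  expect_gt(mean(s) - mean(b), 0) # stress direction

  same <- rep(3, 23)
  res2 <- compare_stages(same, same)
  expect_false(res2$significant)
  expect_gt(res2$p_value, 0.9)
  expect_equal(res2$stat_name, "rank_sum") # degenerate gate falls back

  skewed <- rexp(23)^3
  res3 <- compare_stages(skewed, rexp(23)^3)
  expect_equal(res3$stat_name, "rank_sum")
  res4 <- compare_stages(skewed, rexp(23)^3, fallback = "signed_rank")
  expect_equal(res4$stat_name, "signed_rank")
  expect_error(compare_stages(1:10, 1:9), "pairing")
})

test_that("the gated procedure holds its nominal type-I error", {
  set.seed(23)
  rej <- vapply(1:1000, function(i) {
    compare_stages(rnorm(23), rnorm(23))$significant
  }, logical(1))
  rate <- mean(rej)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("ROC handles the forced examples and ties", {
  expect_equal(roc_curve(c(1, 2), c(3, 4))$auc, 1.0)
  expect_equal(roc_curve(c(1, 3), c(2, 4))$auc, 0.75)
  r <- roc_curve(c(1, 2, 2), c(2, 3, 4))
  # brute-force concordant pairs with half weight for ties
  brute <- mean(outer(c(2, 3, 4), c(1, 2, 2), ">") +
                  0.5 * outer(c(2, 3, 4), c(1, 2, 2), "=="))
  expect_equal(r$auc, brute)
  expect_error(roc_curve(1, c(2, 3)), "at least 2")
})

test_that("tpr and fpr are non-increasing as the threshold increases", {
  set.seed(24)
  for (i in 1:20) {
    r <- roc_curve(sample(1:6, 10, TRUE), sample(2:8, 12, TRUE))
    # thresholds are decreasing along the sweep, so the path must ascend
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
    expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
    expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  }
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(25)
  for (i in 1:500) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    b <- sample(1:10, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * (i %% 2))
    s <- sample(3:12, n2, replace = TRUE) + rnorm(n2, 0, 0.01 * (i %% 2))
    auc <- roc_curve(b, s)$auc
    u <- sum(outer(s, b, ">") + 0.5 * outer(s, b, "=="))
    expect_equal(auc, u / (n1 * n2), tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(28)
  for (i in 1:20) {
    b <- rnorm(15)
    s <- rnorm(12, 0.8)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(0, 15), rep(1, 12)), predictor = c(b, s),
      quiet = TRUE, direction = "<")))
    expect_equal(roc_curve(b, s)$auc, ref, tolerance = 1e-10)
  }
})

test_that("null AUC concentrates at one half", {
  set.seed(26)
  aucs <- vapply(1:500, function(i) roc_curve(rnorm(23), rnorm(23))$auc,
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("label shuffling destroys significance on a strong effect", {
  set.seed(27)
  b <- rnorm(23, 0, 1); s <- rnorm(23, 3, 1)
  expect_true(compare_stages(b, s)$significant)
  pooled <- c(b, s)
  ps <- vapply(1:200, function(i) {
    idx <- sample(46, 23)
    compare_stages(pooled[idx], pooled[-idx])$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.2)
})

test_that("hydration progression counts strictly exceed the cut", {
  entries <- data.frame(subject_id = rep(sprintf("s%02d", 1:23), 3),
                        stage = rep(c("baseline", "scwt", "walking"), each = 23),
                        r = 0.9)
  prog <- hydration_progression(entries, cut = 0.5,
                                stage_order = c("baseline", "scwt", "walking"))
  expect_equal(prog$n_above, c(23, 23, 23))
  entries$r[1] <- 0.5 # exactly the cut: not counted
  expect_equal(hydration_progression(entries, 0.5)$n_above[1], 22)
  # missing subject excluded everywhere with a warning
  entries2 <- entries[-1, ]
  expect_warning(prog2 <- hydration_progression(entries2, 0.5), "excluding")
  expect_equal(prog2$n_above, c(22, 22, 22))
})

test_that("hydrating sites show a rising progression across stages", {
  # three equal stimulus-neutral stages so the progression isolates the
  # hydration ramp (no stress-stage rate boost, no artifacts); a busy event
  # stream keeps per-stage correlation estimates stable
  plan <- data.frame(stage = c("early", "middle", "late"),
                     duration_s = rep(180, 3))
  ann <- annotations_from_plan(plan)
  profs <- list(
    forehead = site_profile("forehead", gain = 0.6, tonic_level_us = 20,
                            tonic_drift_sd = 0.005, responsiveness = 0.1,
                            responsiveness_end = 0.9,
                            spontaneous_scr_rate_per_min = 0.5),
    finger = site_profile("finger", responsiveness = 0.9,
                          tonic_drift_sd = 0.005,
                          spontaneous_scr_rate_per_min = 0.5))
  ok <- vapply(1:10, function(ci) {
    cfg <- simulation_config(n_subjects = 20, stage_plan = plan, fs_raw = 25,
                             scr_rate_baseline_per_min = 6,
                             site_profiles = profs, seed = 700 + ci)
    cohort <- simulate_cohort(cfg)
    entries <- do.call(rbind, lapply(cohort, function(el) {
      seg <- segment_by_stages(el$recording, ann)
      data.frame(subject_id = el$recording$subject_id, stage = plan$stage,
                 r = vapply(plan$stage, function(st) {
                   pearson_r(seg$filtered[[st]][, "forehead"],
                             seg$filtered[[st]][, "finger"])
                 }, numeric(1)))
    }))
    prog <- hydration_progression(entries, 0.5, stage_order = plan$stage)
    all(diff(prog$n_above) >= 0)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
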