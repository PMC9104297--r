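#!/usr/bin/env Rscript
# The cohort-level site comparison: within-subject correlations with the
# finger (reference), normality-gated baseline-vs-stress tests and ROC/AUC
# per site and index, and the noise-band power fraction per site and stage.
# Writes all tidy tables under results/site_comparison/ via the pipeline
# runner, then prints the three comparison axes.

suppressPackageStartupMessages(library(edasite))

scfg <- simulation_config(seed = 20220421)
manifest <- run_pipeline("results/site_comparison", "simulate", scfg = scfg)

report_dir <- "results/site_comparison"
cs <- read.csv(file.path(report_dir, "correlation_summary.csv"))
cat("Within-subject correlation with the finger (mean, SD over 23 subjects):\n")
print(cs, row.names = FALSE, digits = 3)

tests <- read.csv(file.path(report_dir, "tests.csv"))
cat("\nBaseline vs Stroop stage, per site and index:\n")
print(tests[, c("site", "index", "mean_baseline", "mean_stress",
                "stat_name", "p_value", "stars")],
      row.names = FALSE, digits = 3)

sig <- aggregate(significant ~ site, tests, sum)
cat("\nSignificant indices per site (of 5):\n")
print(sig, row.names = FALSE)

auc <- read.csv(file.path(report_dir, "roc_auc.csv"))
cat("\nROC AUC for classifying the stress stage:\n")
print(reshape(auc, idvar = "site", timevar = "index", direction = "wide"),
      row.names = FALSE, digits = 3)

qs <- read.csv(file.path(report_dir, "quality_summary.csv"))
cat("\nMedian noise-band power fraction Pn (raw | 0.6 Hz filtered):\n")
print(qs[order(qs$stage, qs$site), ], row.names = FALSE, digits = 3)
cat("\nExpected pattern: foot Pn spikes while walking and collapses after\n")
cat("filtering; neck/finger Pn rises during weightlifting; forehead is the\n")
cat("most robust to motion. Finger and foot carry the significant stress\n")
cat("indices and the highest correlation with the reference.\n")
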