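#!/usr/bin/env Rscript
# Simulate the study cohort: 23 subjects, four 120 s stages (rest, Stroop
# test, walking, one-handed weightlifting), four recording sites with
# site-specific responsiveness, tonic level and motion-artifact exposure.
# Writes a per-subject/site ground-truth summary used by later steps as a
# sanity reference.

suppressPackageStartupMessages(library(edasite))
dir.create("results", showWarnings = FALSE)

scfg <- simulation_config(seed = 20220421)
cohort <- simulate_cohort(scfg)
ann <- annotations_from_plan(scfg$stage_plan)
write_annotations(ann, "results/stage_annotations.csv")

rows <- list()
for (el in cohort) {
  for (site in el$recording$sites) {
    for (st in scfg$stage_plan$stage) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = el$recording$subject_id, site = site, stage = st,
        true_scr_count = truth_event_count(el$truth, site, st))
    }
  }
}
truth <- do.call(rbind, rows)
write.csv(truth, "results/ground_truth_scr_counts.csv", row.names = FALSE)

agg <- aggregate(true_scr_count ~ site + stage, truth, mean)
agg <- agg[order(agg$site, match(agg$stage, scfg$stage_plan$stage)), ]
cat("Mean true SCR count per 120 s stage (23 subjects):\n")
print(agg, row.names = FALSE, digits = 3)
cat("\nStress stage roughly doubles the event rate at responsive sites\n")
cat("(finger, foot); forehead/neck activity is dominated by spontaneous,\n")
cat("stimulus-independent responses early in the session.\n")
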