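# edasite

Multi-site electrodermal activity (EDA) comparison: can a forehead, neck or
foot electrode stand in for the classic finger site?

Skin conductance is the standard non-invasive readout of sympathetic
arousal, but finger electrodes get in the way of real-world use. This
package implements the full analysis pipeline for comparing body sites
recorded simultaneously:

* **Preprocessing** — resampling to an 8 Hz working rate, zero-phase
  order-6 Butterworth low-pass at 0.6 Hz, stage segmentation.
* **Tonic/phasic decomposition** — per segment, the convex program

  min over p ≥ 0, ℓ, d of ½‖Kp + Bℓ + Cd − x‖² + α‖p‖₁ + (γ/2)‖ℓ‖²

  where `K` convolves a non-negative sparse sudomotor driver `p` with a
  biexponential SCR kernel, `B` is a cubic-spline tonic basis and `C` an
  offset/drift term — solved by an accelerated projected-gradient method
  with an exact active-set polish (C++ core).
* **EDA indices** — per stage and site: SCR count (adaptive threshold:
  0.05 of the segment's maximum phasic peak), phasic mean/variance, tonic
  mean/variance.
* **Signal quality** — `Pn`, the fraction of Welch-periodogram power above
  0.4 Hz (autonomic dynamics live below 0.4 Hz, so that band is motion
  artifact/noise).
* **Statistics** — within-subject Pearson correlations against the
  reference site (raw/phasic/tonic), KS-gated paired t / Wilcoxon rank-sum
  comparisons of baseline vs cognitive stress, ROC/AUC, and a hydration
  progression count (subjects with r > 0.5 per stage).
* **A seeded multi-site simulator** with ground-truth events and component
  traces, emulating a four-stage protocol (rest, Stroop test, walking,
  one-handed weightlifting; 120 s each) across four sites with
  site-specific responsiveness, spontaneous activity, hydration ramps and
  stage-locked motion artifacts.

## Worked example

Simulate one subject under the study conditions, decompose the finger
channel per stage, and compute the standard indices:

```r
library(edasite)

scfg <- simulation_config(seed = 20220421)   # 23-subject study conditions
sim  <- simulate_recording(scfg, 0)          # subject 1 + ground truth
ann  <- annotations_from_plan(scfg$stage_plan)
seg  <- segment_by_stages(sim$recording, ann, pipeline_config())

d <- decompose(seg$filtered[["scwt"]][, "finger"], seg$fs)
compute_indices(d, seg$fs, stage = "scwt", site = "finger", subject_id = "s01")
```

which prints

```
  subject_id   site stage n_scr phasic_mean phasic_variance tonic_mean tonic_variance
1        s01 finger  scwt     7      0.1955         0.03951      6.611       0.003432
```

7 skin conductance responses in the 2-minute Stroop (stress) stage against
6 at baseline (phasic mean 0.195 vs 0.135 µS): the finger tracks the
stress induction. The same subject's ground truth holds 11 and 8 central
events — closely spaced responses merge under the threshold counter, a
known property of this index.

The numbered scripts under `analysis/` run the full study:

1. `01_simulate_cohort.R` — simulate the 23-subject cohort, tabulate
   ground-truth event counts per site and stage.
2. `02_decompose_example.R` — per-stage decomposition of one subject,
   component traces and indices.
3. `03_site_comparison.R` — the cohort-level comparison. Under the default
   conditions it prints, among other tables:

   ```
   Significant indices per site (of 5):
        site significant
      finger           4
        foot           3
    forehead           1
        neck           0

   Median noise-band power fraction Pn (raw | 0.6 Hz filtered):
        site   stage  median_pn_raw  median_pn_filtered
        foot  walking        0.6845              0.1055
        neck  walking        0.2110              0.0266
      finger  weightlifting  0.3899              0.2059
   ```

   Finger and foot carry the significant stress indices (stress-stage AUC
   0.82–0.91 vs ≈ 0.5 at forehead/neck) and the foot correlates best with
   the finger (mean raw r 0.54 vs ≈ 0 for forehead/neck); the foot's
   walking artifact is high-frequency and collapses after the 0.6 Hz
   low-pass, while weightlifting distorts the finger and neck.
4. `04_hydration_progression.R` — subjects whose forehead correlates
   r > 0.5 with the finger per stage; under a fully hydrating ramp the
   count rises 1 → 3 → 13 across a three-stage session.

All tables land under `results/`.

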