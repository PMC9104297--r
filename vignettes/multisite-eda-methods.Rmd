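---
title: "Multi-site EDA comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site EDA comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edasite)
```

# The problem

Electrodermal activity (EDA) — skin conductance driven by eccrine sweat
glands — is usually recorded at the fingers, but palmar sites are
impractical for ambulatory monitoring. This package implements an analysis
pipeline for deciding whether an alternative body site (forehead, back of
neck, inner foot) is a usable substitute for the finger: it compares sites
by (a) within-subject correlation with the finger signal, raw and after
tonic/phasic decomposition, (b) the ability of standard EDA indices computed
at that site to separate a cognitive-stress stage from rest, and (c)
robustness to motion artifact, scored by a spectral noise measure.

Because wearable EDA studies rarely deposit raw recordings, the package
ships a seeded multi-site generator with full ground truth, and the entire
pipeline is validated against that ground truth.

# Signal model

A skin conductance channel is modelled as

$$ y(t) = \mathrm{tonic}(t) + \mathrm{phasic}(t) + \mathrm{artifact}(t) + \varepsilon(t), $$

where the tonic level (SCL) drifts slowly, the phasic component is a train
of skin conductance responses (SCRs) — sudomotor nerve bursts convolved with
a biexponential (Bateman) kernel
$k(\tau) = e^{-\tau/\tau_d} - e^{-\tau/\tau_r}$ — and
$\varepsilon$ is white measurement noise. The decomposition inverts this
model per segment by solving the convex program

$$ \min_{p \ge 0,\ \ell,\ d}\ \tfrac12 \lVert K p + B\ell + C d - x\rVert^2
   + \alpha \lVert p\rVert_1 + \tfrac{\gamma}{2}\lVert \ell \rVert^2 , $$

with $K$ the kernel convolution operator (unit-peak normalised, so driver
magnitudes are on the scale of SCR peak amplitudes), $B$ a cubic B-spline
basis for the tonic curve with knots every 10 s, and $C$ an offset plus
linear drift. The non-negative sparse driver $p$ is the estimated sudomotor
activity; `phasic = K p`, `tonic = B l + C d`, and the residual is defined
as `x - phasic - tonic`, so the reconstruction identity holds exactly.

## Solver

The spline/drift block is eliminated in closed form, leaving a non-negative
LASSO-type problem in $p$ that is solved by accelerated projected gradient
descent (FISTA with monotone restart; step size from a power-iteration
Lipschitz estimate), implemented in C++ with the kernel applied through its
exact second-order recursion ($O(n)$ per apply). Because gradient methods
crawl near the solution, `decompose()` finishes with an active-set *polish*:
an exact solve of the reduced system on the detected driver support,
iterating KKT checks (dropping negative coordinates, admitting violators).
When the trimmed support exceeds `max_support` (300) the polish is skipped —
that regime only occurs on noise-dominated segments where the extra
precision is irrelevant to any downstream index. On short test problems the
polished solution matches an independent dual active-set QP solver to
numerical precision (the test suite checks 1e-4 RMS on the phasic trace).

Defaults $\alpha = 8\times10^{-4}$, $\gamma = 10^{-2}$, knots every 10 s and
$\tau_r/\tau_d = 0.7/2.0$ s follow the established convex-decomposition
convention for EDA. Input is *not* z-normalised: indices are reported in
microsiemens. Decomposition is applied per 120 s stage (indices are
per-stage quantities); nothing prevents decomposing a whole recording in one
call if a user prefers.

# Preprocessing

Recordings are resampled from the acquisition rate (100 Hz) to a working
rate of 8 Hz and low-pass filtered with a zero-phase order-6 Butterworth at
0.6 Hz, comfortably above the < 0.4 Hz band of autonomic EDA dynamics.
Zero-phase (forward-backward) filtering is used so SCR onsets are not
delayed; the effective magnitude response is the squared single-pass
response.

Two implementation details matter more than they appear:

* **Edge handling.** An IIR filter started from a zero state produces a
  start-up transient proportional to the conductance *level* (tens of
  microsiemens), which per-stage decomposition happily converts into fake
  phasic activity in the first stage. `lowpass_filter()` therefore removes
  the straight line through the first and last samples (a zero-phase
  unit-DC-gain filter passes it unchanged), filters the residual with
  odd-reflection padding spanning roughly five settling times of the
  slowest pole, and adds the line back. The padding is longer than the
  minimal `3 * order` samples for exactly this reason.
* **Which signal feeds which module.** The 0.6 Hz low-pass would empty the
  > 0.4 Hz noise band by construction, so the spectral quality metric is
  computed on the *resampled-unfiltered* signal; the decomposition/index
  path consumes the filtered signal. The resampler's anti-alias filter
  (order 8, cutoff `0.4 * fs_out` = 3.2 Hz) deliberately preserves the
  0.4–4 Hz band that the quality metric needs.

Stage segmentation uses half-open intervals `[start, end)`: a sample on a
shared boundary belongs to the later stage.

# EDA indices and SCR counting

Five indices per stage, site and subject: SCR count, phasic mean and
variance, tonic mean and variance (unbiased estimator). SCRs are local
maxima of the phasic trace above an *adaptive* threshold — 0.05 of the
maximum peak amplitude of that segment's phasic signal — making the count
invariant to channel gain. Two guards suppress numerical artifacts: a
minimum inter-peak separation of 1 s, and a topographic prominence
requirement at the same threshold value. The prominence guard exists
because a decaying SCR shoulder sits above the amplitude threshold for tens
of seconds, and any infinitesimal ripple on it would otherwise register as a
response; requiring each counted peak to *rise* by the threshold restores
counts that track the true event number on clean signals. Heavily
overlapped SCRs (inter-event gaps well under the kernel decay) are still
merged — a known, standard limitation of threshold counters.

"Maximum peak amplitude" is interpreted per analysed segment; normalising
across segments would couple stages and break the per-stage reporting.

# Spectral quality: the noise-band power fraction

For a segment $x$, `noise_power_fraction()` computes a Welch periodogram
(Hann window, 32 s segments, 50% overlap, per-window linear detrend) and
reports

$$ P_n = \frac{\int_{0.4\,\mathrm{Hz}}^{f_N} S(f)\,df}{\int_{0^+}^{f_N} S(f)\,df}, $$

the fraction of fluctuation power above 0.4 Hz, up to the 4 Hz Nyquist of
the working rate. Autonomic activity lives below 0.4 Hz, so higher $P_n$
means more motion artifact. Per-window detrending is essential: with the
conductance mean included, total power is dominated by the DC bin and $P_n$
degenerates towards zero for any signal. A constant segment has no
fluctuation power at all; the report then flags `degenerate` rather than
inventing a ratio. The 32 s window is a compromise: ≥ 6 averaged windows on
a 120 s stage, with 1/32 Hz resolution around the 0.4 Hz band edge.

# Statistics

* **Within-subject correlations** are Pearson coefficients between a site
  and the reference (finger) over the continuous movement-free window
  (baseline + stress, 4 min), computed for the raw filtered signal and for
  the phasic and tonic components of a decomposition of that window.
* **Stage comparisons** screen each group with a one-sample
  Kolmogorov–Smirnov test on standardised values; if both groups pass, a
  two-sided paired t-test is used (observations pair by subject), otherwise
  a two-sided Wilcoxon rank sum test. The rank-sum fallback is unpaired by
  construction; a signed-rank option is available for users who want a
  consistently paired procedure. No multiple-testing correction is applied
  across the 5 indices x 4 sites (raw p-values are reported, with the usual
  star convention); a user can apply `p.adjust` downstream. An all-ties
  comparison (zero variance in both groups) is reported as p = 1.
* **ROC/AUC**: thresholds sweep the distinct observed values; a sample is
  predicted "stress" when its value is at least the threshold; AUC is the
  trapezoid area, identical to the normalised Mann–Whitney U (tested
  property). Indices that *decrease* under stress yield AUC < 0.5 and are
  reported as-is, not flipped.
* **Hydration progression** counts subjects with correlation strictly
  greater than 0.5 per stage, excluding subjects missing in any stage.

The KS gate is the plain one-sample test against a standard normal after
standardisation (not Lilliefors-corrected); with n = 23 it is a mild gate,
which matches how the procedure is used in this field.

# The synthetic cohort: what it emulates and what it does not

`simulate_recording()` mirrors the decomposition model. Central sudomotor
events are a homogeneous Poisson process (3/min at rest, doubled during the
stress stage); each site keeps an event with its *responsiveness*
probability, draws an amplitude from a truncated normal (mean 0.4 µS, SD
0.2 µS) scaled by the site gain, and convolves with the unit-peak kernel.
Tonic is a per-site level (finger 6.5, foot 5.5, neck 4.2, forehead 25 µS —
forehead SCL runs much higher than distal sites) with a smoothed random-walk
drift and a log-normal between-subject factor (CV 0.2). Measurement noise
is white, SD 0.01 µS, the resolution class of current wearable EDA
hardware.

Site character comes from four mechanisms, each chosen to reproduce a
qualitative feature of real multi-site recordings:

* **Shared central drive with per-site thinning** — cross-site correlation
  is controlled by responsiveness and gain, not wired in directly.
* **Spontaneous, stimulus-independent SCRs** (forehead 5/min, neck 2/min,
  distal sites 0.5/min) — the forehead is electrodermally *busy* (its SCR
  counts and phasic amplitudes are substantial) yet its activity does not
  track the stress stage. Without this term a weak-but-constant stimulus
  coupling would still be detected by a paired test across 23 subjects,
  which contradicts how unhydrated sites behave.
* **A lag-phase hydration ramp** for forehead and neck: responsiveness
  starts at zero and rises quadratically in time towards 0.3 / 0.25 by the
  session end, with between-subject spread (SD 0.1) on the endpoint. Skin
  hydration takes tens of minutes, so within an 8-minute session the early
  (baseline and stress) stages see essentially no stimulus coupling while
  later stages begin to respond — which is also what makes the
  per-stage correlation counts rise over the session.
* **Stage-locked artifacts**: band-limited 0.4–4 Hz gait noise on the foot
  while walking (SD 0.2 µS; the band is chosen so the artifact survives the
  100 → 8 Hz resampling, as it does in practice where gait energy sits at
  1–3 Hz), and Poisson-timed ~1 s electrode-motion transients during
  weightlifting (finger 8/min at ±2 µS, neck 6/min at ±1 µS), square pulses
  with raised-cosine edges — the simplest testable surrogate for electrode
  displacement.

Ground truth (event times, amplitudes, component traces) is returned with
every recording, and `samples = tonic + phasic + artifact + noise` holds
exactly, so the residual recovers the noise realisation.

What the generator does **not** emulate: electrode drift artifacts at rest,
respiration or temperature coupling, non-Poisson burst clustering,
footwear/humidity effects, or any mechanistic hydration physiology (the
ramp is phenomenological). Consequently, a passing test suite demonstrates
that the *pipeline* recovers what this model generates under realistic
noise — not that any specific human dataset would reproduce specific
numbers.

# Numerical choices and degenerate inputs

* Solver tolerance 1e-8 (relative objective change, 5 consecutive
  iterations) with a 10 000-iteration cap; non-convergence is reported on
  the result and `compute_indices()` refuses such inputs.
* A constant segment decomposes to zero driver by construction and its
  quality report is flagged degenerate.
* The digital Butterworth (bilinear design) attenuates *faster* above
  cutoff than the analog magnitude formula; tests therefore treat the
  analog value as an upper bound on the measured 1 Hz attenuation rather
  than a two-sided target.
* Resampling uses linear interpolation after the anti-alias filter; at a
  12.5x oversampled, band-limited input the interpolation error is below
  0.01%. `signal::resample` was rejected after measuring ~0.19 µS passband
  error on a constant input.
* Seeds: every simulation derives per-subject seeds deterministically from
  the master seed, so cohorts are reproducible bit-for-bit and
  `simulate_recording(cfg, i)` equals element `i + 1` of
  `simulate_cohort(cfg)`.

# Problem sizes used in validation

The test suite and the acceptance script run the full study conditions: 20
independent cohorts of 23 subjects, four sites, four 120 s stages at 100 Hz
(about 5 minutes of compute for the cohort block on one core). Monte-Carlo
calibration checks use 100–1000 replicates at the sizes stated in the
tests; unit tests of the end-to-end plumbing run a reduced protocol (6
subjects, 60 s stages, 25 Hz) purely to keep the default check fast.

# Known limitations

* The rank-sum fallback ignores pairing; the paired t branch dominates in
  practice because the KS gate at n = 23 is weak.
* Threshold-based SCR counting merges closely spaced responses and, on
  noise-dominated channels, counts residual noise peaks; the adaptive
  threshold makes counts comparable across gains but not across noise
  regimes.
* The tonic spline absorbs any phasic baseline shift slower than its 10 s
  knot spacing; sustained SCR summation during dense bursts is partly
  attributed to tonic.
* $P_n$ compares *fractions*: a site with almost no EDA power can show a
  high $P_n$ from tiny absolute noise. Comparisons are therefore made
  within site across stages, or across sites at matched stages.
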