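---
title: "Monitoring Parkinson's disease in daily life: methods behind wearesm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring Parkinson's disease in daily life: methods behind wearesm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring problem

Parkinson's disease symptoms fluctuate over the day: under dopaminergic
medication patients alternate between well-controlled *ON* periods and *OFF*
periods in which tremor, bradykinesia and rigidity re-emerge. Clinic-based
rating scales sample this process once, in an artificial setting. A
daily-life monitoring system instead combines two streams:

* **Wearable sensors** — three 6-DOF IMUs (left wrist, right wrist, chest),
  each recording tri-axial acceleration (range ±8 g) and angular rate
  (±2000 deg/s) at 200 Hz, worn from charger removal in the morning until
  charging at night. The instructed wearing window is 08:00–22:00 local
  time (840 min).
* **Experience sampling (ESM)** — brief smartphone questionnaires: one
  26-item "continuous" questionnaire at a semi-random moment inside each
  2-hour block between 08:00 and 22:00 (7/day), plus a 5-item morning and
  8-item evening questionnaire. Continuous questionnaires must be opened
  within 15 min of the beep; only fully answered questionnaires count.
  Answers are 7-point Likert items (1 = not at all, 7 = very much), e.g.
  "I experience tremor".

The ESM answers act as a parallel subjective ground truth for the sensor
stream. `wearesm` implements the full analysis chain — wear-time accounting,
completion/coverage statistics, pre-questionnaire feature extraction, and
cross-validated OFF-moment prediction — together with a synthetic cohort
generator that makes every stage testable without patient data.

## Wear-time accounting

The device records whenever it is off the charger, so recorded ≠ worn.
Non-wear is detected from the per-minute population standard deviation of
the longitudinal (x) acceleration, computed on complete 60-s blocks aligned
to the session start (a trailing partial minute is dropped). A minute is
non-worn only when its own standard deviation **and** those of the
preceding and following minutes are all below 0.002 g; the threshold
reflects the noise floor of an off-body sensor. Two fixed choices the rule
itself does not dictate:

* *Edge minutes* apply the rule one-sided — only neighbours that exist must
  be sub-threshold. This is the minimal consistent extension.
* *Population* (not sample) standard deviation; with 12 000 samples per
  minute at 200 Hz the distinction is numerically irrelevant, but tests
  need one fixed convention.
* Gravity is **not** removed: a worn, resting sensor still shows ~1 g on
  some axis with physiological micro-variation above the threshold, while
  an off-body sensor is genuinely constant.

Wear time is reported in three categories — worn within the instructed
08:00–22:00 frame, non-worn within it, worn outside it — with
`nonworn_within = 840 − worn_within`, so unrecorded (charging) time counts
as non-worn. Minutes are averaged over the three sensors, then over days,
then over participants (`aggregate_wear()`), matching how group means such
as "788 min worn within the frame" are formed.

## ESM accounting

`generate_schedule()` draws each continuous beep uniformly inside its
2-hour block, redrawing until consecutive beeps are at least 15 min apart
("semi-random" without back-to-back beeps across a block boundary). The
morning questionnaire is available 06:00–12:00 and the evening one
18:00–24:00; these windows are configurable defaults, as the protocol only
fixes that such windows exist. Completion requires every item answered and,
for continuous questionnaires, opening within the 15-min deadline. A
participant's ESM data are considered valid when at least one third of the
continuous questionnaires were completed. Group rates average counts per
participant first, then across participants.

A completed questionnaire is usable for sensor analysis only if all three
sensors have data over the full 15 min before `opened_at`
(`has_sensor_coverage()`); a cumulative gap of ≤ 1 s is tolerated so a
single-sample seam does not reject a window while any real gap does.
After non-wear filtering the same check runs against worn-minute intervals
rather than raw session spans.

## Pre-questionnaire features

For each usable questionnaire, the 15 min preceding `opened_at` are
extracted (answers are given *after* opening, so answering time can never
leak into the window; `extract_segment()` also asserts
`started_at ≥ opened_at`) and split into non-overlapping sub-windows of
`w` seconds (default 60 s; the trailing remainder is dropped). Per
sub-window and channel, five families:

* **Log band energy, 3.5–7.5 Hz** — natural log of the mean-removed
  rectangular-window periodogram power summed over bins with
  `3.5 ≤ f < 7.5` Hz, floored at `1e-12`. The periodogram is normalized so
  the sum over all bins equals the mean square of the demeaned signal
  (Parseval), making the value interpretable as log signal power. The band
  straddles the classic 4–6 Hz parkinsonian rest-tremor frequency.
* **RMS of the 3 Hz low-pass signal** — 4th-order Butterworth applied
  forward–backward (zero phase) over the window extended by symmetric
  (even) edge reflection, with the padding length set by the slowest
  pole's settling time; even reflection keeps the pad's local mean equal
  to the signal's, so no spurious in-band step reaches the filter. The
  feature captures voluntary-movement energy below the tremor band.
* **Dominant frequency and dominant energy ratio** — location of the
  periodogram maximum over positive frequencies, and the power in that bin
  ±1 neighbour divided by total non-DC power. The ±1-bin convention is a
  package choice (the quantity has no canonical definition) and absorbs
  spectral leakage of a tone that falls between bins.
* **Amplitude range** — `max − min` of the raw, unfiltered window.
* **Maximum normalized cross-correlation and its lag** — Pearson
  correlation at every integer-sample lag within ±1 s, for the 9
  within-sensor accelerometer × gyroscope channel pairs; ties break toward
  the smaller |lag|, then the negative lag. Within-sensor pairing is the
  minimal reading of "all accelerometer and gyroscope channels";
  cross-sensor pairs would square the dimension for little obvious gain.

Sub-window values are aggregated by the mean (configurable), giving
3 sensors × (6 channels × 5 + 9 pairs × 2) = 144 features per
questionnaire. Accelerometer features are in g, gyroscope in deg/s; the
cross-correlation is scale-free, so no unit mixing occurs.
`build_instance()` shares channel FFTs and prefix sums across the 9 pairs
for speed; a test pins it to the reference `max_norm_xcorr()`
implementation pair by pair.

## OFF-moment prediction

The OFF label of an instance comes only from the ESM answers: a designated
Likert item (by default item 1, the tremor-experience item) with inclusive
cutoff ≥ 5 of 7. The item index and cutoff are configuration, not
discoveries of the package.

`crossval_off()` evaluates a *simple logistic regression* in stratified,
seeded 10-fold cross-validation. Per fold, features are z-scored with
training-fold statistics only, and the model carries a light ridge penalty
(`glmnet`, α = 0, λ = 10⁻³): with 144 partially collinear features this is
numerically equivalent to near-unregularized logistic regression while
remaining stable when a fold separates perfectly. Fold assignment ignores
temporal ordering (plain stratified CV); adjacent questionnaires are
correlated through the latent state, so a grouped split can be imposed via
the `fold` argument when that assumption matters. `roc_auc()` builds the
ROC over all distinct score thresholds with ties crossing simultaneously
and integrates by trapezoid — algebraically the Mann–Whitney statistic with
ties counted ½, which the tests verify against an explicit pair count and
against pROC.

## The synthetic cohort

No public recordings exist for this protocol, so `sim_config()` /
`simulate_cohort()` define the canonical input source; real data would
enter through the same CSV schemas (`read_recording()`,
`read_esm_responses()`).

* **Latent state** — a two-state alternating-renewal process with
  exponential dwell times, mean 50 min OFF / 100 min ON (a stationary OFF
  fraction of ⅓; fluctuation dynamics are otherwise unreported for this
  population, and a majority-ON day is clinically typical for treated
  patients). The initial state is drawn with the stationary probability.
* **Signal model** — per sensor-day: constant 1 g gravity at a random
  orientation, plus band-limited (< 3 Hz) voluntary-activity noise of
  0.1 g shared across the sensor's channels with random per-channel gains
  (rigid-body movement moves all axes together, which is what gives the
  accel × gyro cross-correlations structure), scaled ×0.5 during OFF
  (bradykinesia), plus a 5 Hz tremor sinusoid of amplitude 0.2 g during
  OFF and 0.02 g during ON, plus 0.02 g white noise. Gyroscope channels
  are analogous without gravity, scaled by 50 (deg/s)/g. Non-wear
  (Poisson 2 events/day, exponential mean 26 min — expected 52 min/day,
  the reported cohort mean — simultaneous on all sensors, as for a shower)
  collapses the signal to gravity plus a 5 × 10⁻⁴ g floor, deliberately
  below the 0.002 g threshold so the detector is testable on both sides.
* **ESM responses** — continuous questionnaires completed with probability
  0.79 (morning 0.97, evening 0.94, the three reported completion rates);
  completion duration averages 219 s. The designated OFF item is a rounded,
  clamped Gaussian with mean 6 during latent OFF and 2 during ON (sd 0.8),
  giving imperfect but learnable subjective labels; remaining items are
  neutral noise.

Everything derives deterministically from `rng_seed` via per-entity
sub-seeds, so cohorts are reproducible stream by stream.

What the generator deliberately does **not** model: gait or other
structured movement, dyskinesia, freezing, posture changes within a day,
sensor drift or clock skew, and item-level questionnaire semantics beyond
the single OFF item. Passing tests therefore demonstrate that the pipeline
recovers the *planted* structure, not that real parkinsonian OFF states
are detectable at any particular accuracy; the single-patient report this
design follows is encouraging but not reproducible without its raw data.

## Numerical and scale choices

* Timestamps are integer milliseconds since the Unix epoch (UTC); clock
  protocols (08:00–22:00) are resolved through a per-participant timezone.
  All intervals are half-open `[t0, t1)` so minutes and windows tile
  without overlap, and slicing is exact under the nominal-rate timestamp
  reconstruction `start + i/fs`.
* Out-of-range samples clip to ±8 g / ±2000 deg/s on file reading (sensors
  saturate; clipping is counted and warned about, not an error).
* Simulation studies in the test-suite run at 16–32 Hz sampling rather than
  the device's 200 Hz: every spectral component of the generator (gravity,
  < 3 Hz activity, 5 Hz tremor, the 3.5–7.5 Hz feature band) lies below
  8 Hz, so a 16 Hz cohort carries the same information per window at a
  twelfth of the cost, and the wear-time rule operates on per-minute
  statistics that are rate-invariant. The end-to-end OFF-prediction study
  uses 8 participants × 14 days (≈ 530 usable questionnaires, subsampled
  to 500) — the protocol's per-participant dimensions at a cohort size
  chosen to give a stable AUC estimate.
* The evaluation's null condition sets equal tremor amplitudes and equal
  activity scales across states, removing every path from the latent state
  into the signal while keeping the labels; cross-validated AUC then has
  nothing to find and sits at chance.

## Known limitations

* The non-wear rule cannot flag the first and last minute of a removal
  episode (their blocks mix worn and off-body signal, and their neighbours
  are above threshold); accounting and acceptance checks therefore speak
  of *interior* non-wear minutes.
* Coverage, and hence instance counts, drop for questionnaires opened just
  after 22:00 (the session ends with the instructed frame) — the same
  censoring the real protocol exhibits.
* With compliance modelled at the event level, partially answered
  questionnaires never occur in simulation, although the accounting
  handles them.
* The OFF label derives from one item; composite or clinician-anchored
  labels are out of scope.
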