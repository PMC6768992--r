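# wearesm

Analysis tools for daily-life Parkinson's disease monitoring studies that
pair body-worn inertial sensors with experience-sampling (ESM)
questionnaires.

In such a protocol, patients wear three 6-DOF IMUs (left wrist, right
wrist, chest; ±8 g accelerometer, ±2000 deg/s gyroscope, 200 Hz) during the
instructed 08:00–22:00 timeframe for two weeks, while a smartphone app
issues a 26-item questionnaire at a semi-random moment in each 2-hour block
(7/day, to be opened within 15 min) plus short morning and evening
questionnaires. The subjective answers — e.g. "I experience tremor" on a
1–7 Likert scale — serve as a parallel ground truth for the sensor stream.

`wearesm` implements the full chain:

* **ESM engine** — semi-random beep scheduling, completion accounting
  (only fully answered questionnaires count; continuous ones must be opened
  within 15 min), the one-third validity rule, and the all-three-sensor
  15-min pre-questionnaire coverage check.
* **Wear time** — non-wear detection from the per-minute standard
  deviation of the x-axis acceleration (a minute is non-worn when it and
  both neighbours fall below 0.002 g) and the three-category wear summary
  (worn within / non-worn within / worn outside the 840-min frame),
  averaged over sensors, days, participants.
* **Features** — per 15-min pre-questionnaire window, divided into
  sub-windows of length *w*: log signal energy in the 3.5–7.5 Hz tremor
  band, RMS of the 3 Hz low-pass signal, dominant frequency and dominant
  energy ratio, raw amplitude range, and the maximum normalized
  accelerometer × gyroscope cross-correlation with its temporal offset —
  144 features per questionnaire.
* **OFF prediction** — instance labels from a designated Likert item
  (inclusive cutoff ≥ 5), stratified 10-fold cross-validated logistic
  regression, ROC curve and AUC: P(OFF instance scores above non-OFF
  instance), ties ½.
* **Synthetic cohorts** — a generator with a latent alternating-renewal
  ON/OFF trajectory modulating tremor and activity, planted non-wear, and
  compliance-realistic ESM responses, so the entire pipeline is testable
  without patient data. Real recordings enter through the same CSV schemas.

## Worked example

```r
library(wearesm)

## the two-week ESM protocol
sched <- generate_schedule(n_days = 14, start_date = "2026-01-05", seed = 42)
table(sched$kind)
#> continuous    evening    morning
#>         98         14         14

## a small synthetic cohort (16 Hz keeps the example light; every spectral
## component of the generator lies below 8 Hz)
cfg <- sim_config(n_participants = 2, n_days = 2, sampling_rate_hz = 16,
                  rng_seed = 42)
cohort <- simulate_cohort(cfg)

p1 <- cohort$participants[[1]]
completion_report(p1$events, p1$responses)$by_kind
#>                  kind n_issued n_completed rate_percent
#> continuous continuous       14          10     71.42857
#> morning       morning        2           2    100.00000
#> evening       evening        2           2    100.00000

## wear-time accounting for one sensor-day
sess <- p1$sessions[[1]]$left_wrist
ms   <- minute_std(sess)
worn <- classify_worn(ms$std_x)          # the 0.002 g triple-minute rule
summarize_wear(worn, ms$minute_start_ms)
#>    worn_within_min nonworn_within_min   worn_outside_min
#>                772                 68                  0
```

Ten of fourteen continuous questionnaires were completed (71% — above the
one-third validity floor), and on this simulated day the sensor was worn
772 of the 840 instructed minutes; the 68 non-worn minutes are the planted
removal episodes plus their partially-covered edge minutes and the
unrecorded remainder of the frame.

The end-to-end prediction study — simulate a cohort, filter non-wear,
extract pre-questionnaire windows, compute features, cross-validate —
is one call:

```r
res <- run_off_pipeline(sim_config(n_participants = 8, n_days = 14,
                                   sampling_rate_hz = 16,
                                   rng_seed = 20260923),
                        max_instances = 500)
res$auc   # cross-validated AUC for detecting subjectively reported OFF
```

See `vignettes/methods.Rmd` for the model, parameter meanings and the
design choices behind every stage.

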