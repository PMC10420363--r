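# gaitevents

Automated detection of gait events — **initial contact** (IC) and **foot
off** (FO) — from lower-limb motion-capture marker trajectories, for
clinical three-dimensional gait analysis.

Gait cycle events segment walking into stance and swing; every
spatiotemporal, kinematic and kinetic variable a gait laboratory reports
depends on them. The gold standard (force-plate thresholding) covers only
the few steps that land on a plate, and manual annotation is slow and
subjective. `gaitevents` provides two automated detectors behind one
evaluation protocol:

* **Recurrent frame classifier.** Each trial becomes a `T x 36` tensor:
  positions and velocities (AP, ML, vertical) of the left/right heel,
  toe and ankle markers, min-max normalized per trial and channel onto
  [0.1, 1.1]. A stacked bi-directional LSTM (implemented from scratch in
  RcppArmadillo: forward pass, backpropagation through time, Adam) maps
  frames to probabilities of *no event / left event / right event*; one
  independent model per event type, trained with weighted categorical
  cross-entropy (event frames weighted `w:1`, default 10, against the
  extreme class imbalance of single-frame targets), masking for
  zero-padded batches, and peak detection (threshold 0.01) to emit
  events. The reference architecture is 3 layers x 200 hidden units,
  dropout 0.4, weight ratio 1:10, selected from a
  3 x 7 x 3 x 4 = 252-point grid.
* **Velocity-threshold heuristic** (Ghoussayni-style baseline): IC at the
  gated minimum of heel sagittal speed after its descending threshold
  crossing, FO at the ascending crossing of toe sagittal speed through
  `1.9 v` (`v` = walking speed), with training-set threshold fitting.
* **Evaluation protocol:** optimal one-to-one event matching with the
  ±4-frame / ±50-frame tolerance windows (at 150 Hz: ±26.7 ms TP window,
  ±333.3 ms FP window, 6.7 ms per frame), MAE with bootstrap 95% CI,
  detection rate TP/(TP+FP+FN), cumulative detection curves, and paired
  Wilcoxon signed-rank comparison with Bonferroni correction and effect
  size `r = |Z|/sqrt(N)`.
* **Synthetic gait simulator:** parametric walking personas (strike
  pattern, cadence, stance fraction, stride variability, foot drag,
  marker noise) whose trials carry construction-exact ground-truth
  events, so the whole pipeline is testable end to end without clinical
  recordings.

Minimal C3D file I/O, a JSON dataset fixture format, subject-level
train/validation/test splitting with pathology holdout (zero-shot
evaluation) and a one-call experiment driver round out the package. See
`vignettes/gait-event-detection.Rmd` for the methods account.

## Worked example

```r
library(gaitevents)

profile <- preset_profiles()[["HC-heel"]]   # heel-striking walker, 2 mm marker noise
trial <- simulate_trial(profile, subject_id = "S01", trial_id = "S01-T01", seed = 42)
print(trial)
#> <gait_trial> S01-T01 (subject S01, SYNTH-HC-heel)
#>   1200 frames @ 150 Hz (8.00 s), 30 events (30 TRUTH)
head(trial$events, 4)
#>   etype side frame source
#> 1    IC    L    38  TRUTH
#> 2    FO    R    57  TRUTH
#> 3    IC    R   118  TRUTH
#> 4    FO    L   138  TRUTH

detected <- detect_events_heuristic(trial)
res <- pool_matches(lapply(c("L", "R"), function(sd) {
  match_events(detected[detected$etype == "IC" & detected$side == sd, ],
               trial_events(trial, etype = "IC", side = sd), fs = trial$fs)
}))
detection_rate(res)
#> [1] 0.9333333
temporal_error_summary(res, seed = 1)
#> IC MAE 17.3 ms (95% CI 12.0-22.7, n = 15)
```

The heuristic finds 14 of 15 initial contacts of this noisy heel-strike
trial within the ±4-frame window, with a mean absolute error of about
17 ms (2.6 frames at 150 Hz).

A full experiment — simulate a three-profile cohort, hold the
foot-drag profile out of training entirely, train both detector models,
fit the heuristic thresholds, evaluate per pathology class:

```r
profs <- preset_profiles()
cohort <- cohort_spec(list(
  list(profile = profs[["HC-heel"]], n_subjects = 10, trials_per_subject = 3),
  list(profile = profs[["ICP-forefoot"]], n_subjects = 10, trials_per_subject = 3),
  list(profile = profs[["DF-forefoot-drag"]], n_subjects = 5, trials_per_subject = 3)
), seed = 404)
det <- function(et) detector_config(et, n_layers = 1, hidden_units = 32,
                                    dropout = 0.2, epochs = 15, batch_size = 4,
                                    seed = 11)
ex <- run_experiment(experiment_config(
  cohort, holdout_classes = "SYNTH-DF-forefoot-drag",
  ic_config = det("IC"), fo_config = det("FO"), seed = 404))
print(ex)
#> <gait_experiment>
#>   36 train / 6 val / 33 test trials, seed 404
#>   MODEL     IC: MAE   7.7 ms (7.2-8.2), detection rate 100.0%
#>   MODEL     FO: MAE   8.6 ms (8.0-9.2), detection rate 100.0%
#>   HEURISTIC IC: MAE  54.9 ms (52.2-57.5), detection rate 23.9%
#>   HEURISTIC FO: MAE   7.6 ms (7.4-7.8), detection rate 99.4%
```

The learned detector localizes both event types to ~1 frame on every
class — including the drag profile it never saw in training (zero-shot
IC MAE 10.5 ms, detection rate 100%) — while the heel-based heuristic IC
rule collapses on the two forefoot-striking classes that dominate this
test set. `write_report(ex, "report/")` emits the metrics tables
(`metrics.csv`) and a versioned JSON report; `plot(ex$detectors$IC)`
shows the training curves.

A thin command-line wrapper over the same functions ships in
`inst/scripts/gaitevents.R` (`simulate`, `train`, `detect`,
`heuristic-detect`, `evaluate`, `run`).

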