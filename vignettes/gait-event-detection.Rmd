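---
title: "Detecting gait events from marker trajectories: models, simulator and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical three-dimensional gait analysis segments walking into gait cycles
bounded by two events per foot: **initial contact** (IC), when the foot
first touches the ground, and **foot off** (FO), when it leaves it. The
gold standard detects these events by thresholding the vertical ground
reaction force on floor-embedded force plates, but force-plate contacts are
sparse and often unusable in pathological gait (foot drag, small steps,
walking aids). Automated detection from the optical marker trajectories
themselves is therefore standard practice, either with velocity-threshold
heuristics or with learned sequence models.

`gaitevents` implements both families end to end:

* a **frame-labelling detector**: a stacked bi-directional LSTM that maps
  the 36-channel trajectory representation of a trial to per-frame
  probabilities of *no event / left event / right event*, one independent
  model per event type, with peak-detection post-processing;
* a **velocity-threshold heuristic** in the style of Ghoussayni's
  foot-marker speed rules, with training-set threshold fitting;
* the **evaluation protocol**: tolerance-window event matching, temporal
  error (MAE with 95% CI), detection rate, cumulative detection curves and
  paired nonparametric method comparison;
* a **synthetic gait simulator** that produces trials with ground-truth
  events known by construction, so every stage is testable without access
  to clinical recordings.

## The detector model

A trial is represented as a `T x 36` matrix: for each of the six markers
(left/right heel, toe, ankle) the three position axes (anterior-posterior,
medio-lateral, vertical; mm) and their first derivatives. Derivatives are
computed by central differences on the raw millimetre trajectories
*before* normalization, then every channel is min-max normalized per trial
onto [0.1, 1.1]. Per-trial statistics (rather than dataset-global ones)
make the representation invariant to laboratory origin, capture-volume
size and absolute walking speed; the offset to 0.1 keeps real frames
distinguishable from the all-zero right-padding that batches use, which
the model's masking front strips before the recurrence.

The classifier is `n_layers` bi-directional LSTM layers of `hidden_units`
per direction, dropout after every recurrent layer (training only), and a
time-distributed dense layer with 3-way softmax. The loss is categorical
cross-entropy with per-frame sample weights: event frames weigh `w`
("non-event to event ratio 1:w") because single-frame targets are extremely
sparse — of the order of one event frame per two hundred non-event frames
in clinical recordings. Labels are single-frame by design; sparsity is
compensated by the weights, not by widening the targets. The reference
configuration, selected by grid search over
{1,2,3} layers x {50..350} units x dropout {0.2,0.4,0.6} x weight ratios
{10,100,500,1000} (252 combinations), is 3 layers x 200 units, dropout
0.4, ratio 1:10; package defaults mirror it. Optimizer settings (Adam,
learning rate 2e-3, batch size 8, epoch count) are package choices —
the selection protocol does not pin them down.

Training and validation trials are first cropped to the span of their
annotated events plus an independently drawn buffer of 25–125 frames per
side, so the model never learns that events sit at fixed trial offsets.
Two separate models are trained for IC and FO: a single joint model is
known to fail on first/last events near trial boundaries, and separate
models allow separate hyperparameters.

The implementation is a from-scratch bi-directional LSTM
(forward/backward passes in RcppArmadillo with full backpropagation
through time, Adam in R). Gradients are verified against central finite
differences in the test suite, and the loss is cross-checked against an
independently coded weighted cross-entropy. Recurrence always runs over
the unpadded prefix of a sequence only, which makes masking invariance
exact rather than approximate: right-padding cannot change the loss or any
real-frame prediction.

## From probabilities to events

Events are read off each class's probability sequence by peak detection
with threshold 0.01. Two documented choices go beyond that rule: candidate
peaks closer than `min_separation` (default 25 frames at 150 Hz, about
167 ms — well below any physiological same-side inter-event interval and
above the jitter width of a learned peak) are resolved by a weighted
interval scheduling dynamic program that keeps the subset of peaks with
maximal total probability mass; plateau maxima are attributed to their
first frame. A pairwise "keep the higher peak" suppression was considered
and rejected: it is not optimal in total retained mass (three equal-ish
peaks at spacing just under the separation), whereas the DP solution is,
and the test suite verifies it against exhaustive enumeration.

## The heuristic baseline

The baseline detects IC at gated local minima of the heel marker's
sagittal-plane speed `sqrt(v_AP^2 + v_V^2)` and FO at ascending crossings
of the toe speed through `1.9 v`, where `v` is the trial's walking speed.
The operating point TH_IC = 0, TH_FO = 1.9v is the clinically fitted one;
`fit_thresholds()` re-fits both on any training set by grid search on
matched-event MAE. Choices the protocol leaves open, resolved here:

* *Walking speed* is the absolute mean AP velocity of the mid-ankle point
  over the trial (per trial, not per subject) — it uses only markers the
  method already requires and is direction-agnostic.
* *TH_IC = 0* cannot be a crossing threshold for a non-negative speed; it
  is read as "the heel-speed minimum at stance onset", gated by `0.2 v`:
  a candidate arises where the smoothed heel speed falls through the gate
  (the end-of-swing deceleration) and is placed at the speed minimum
  within a short search window after the crossing (default 12 frames at
  150 Hz, the duration of the final heel deceleration), then refined to
  the minimal unsmoothed speed within the smoothing window. Gating the
  minimum to the post-crossing window is what makes the rule robust to
  marker noise, which otherwise scatters spurious sub-gate minima across
  the whole stance plateau.
* The AP and vertical velocity components are smoothed by a centered
  5-frame moving average (scaled with sampling rate) before the speed
  magnitude is taken — equivalent to differentiating a smoothed
  trajectory, and what keeps the stance-phase noise floor well below the
  gate. Candidates closer than the separation keep the earlier frame.

On heel-strike gait these rules recover events to within 1–2 frames. On
forefoot-strike gait the heel-based IC rule is systematically late by the
heel-toe contact delay — the structural weakness that motivates learned
detectors, and a behaviour the simulator reproduces by construction.

## The synthetic simulator

`simulate_trial()` builds each foot from a cyclic phase schedule: during
stance the foot's markers are ground-fixed; during swing the foot advances
by one stride along a smooth interpolant with a vertical clearance arc;
feet are anti-phased. It is a *kinematic signature generator*, not a
biomechanical model: only the event-adjacent features that detectors key
on are modelled.

* The swing AP profile is the Beta(1.5, 3) CDF of normalized swing phase:
  velocity rises steeply right after lift-off (the push-off signature the
  FO threshold rule needs) and decays smoothly into touchdown (C^1, zero
  end velocities). The vertical arc is `sin^2(pi s)` with per-marker
  clearance; `drag_severity` scales the toe clearance down by up to 90%.
* Strike pattern: the strike-leading marker (heel for HEEL, toe for
  FOREFOOT, both for MIDFOOT) touches down first; the other follows after
  `|heel_toe_offset_ms|`. IC is the leading marker's first stance frame,
  FO the first frame after the toe's last stance frame — ground truth is
  exact in frames because contact times are snapped to the frame grid.
* Randomness: per-cycle stride jitter (`step_length_cv`), per-subject
  multiplicative speed/cadence jitter (3% SD) in cohorts, and additive
  white Gaussian marker noise (`noise_sd_mm`, default 2 mm — the order of
  residual noise after standard trajectory filtering). Everything is
  seeded and bitwise reproducible.
* Geometry constants (heel/toe/ankle ground offsets 25/15/70 mm, foot
  length 160 mm, lateral half-width 80 mm) are conventions, not anatomy.

Five presets ship as test personas loosely echoing a clinical cohort: a
heel-striking control, a forefoot striker, a forefoot striker with severe
drag, a short-stride fast-cadence walker, and a baseline. Default study
conditions are self-selected speeds of 0.85–1.25 m/s, cadences of 108–128
steps/min, 8 s trials at 150 Hz.

What the simulator does **not** emulate: soft-tissue artefact and marker
occlusion, turning or treadmill gait, kinetic variables, within-trial
fatigue, and the full heterogeneity of real pathological gait. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
mechanics are correct and that the detector can learn event signatures at
single-frame precision from noisy trajectories — they do not certify
clinical accuracy numbers, which require real force-plate-annotated data.

## Evaluation protocol

Matching is per (event type, side) stream. Each reference event is
assigned at most one prediction within +/-50 frames by an assignment that
maximizes the number of matched pairs and then minimizes total absolute
error (a non-crossing dynamic program over the sorted streams, which is
optimal for absolute-difference costs on a line; the tests verify equality
with exhaustive enumeration). A matched pair within +/-4 frames
(+/-26.7 ms at 150 Hz) is a true positive, within +/-50 frames a false
positive; unmatched reference events are false negatives, so every
reference event receives exactly one outcome. Unmatched predictions are
reported as *spurious* and excluded from the three counts by default — the
protocol's counting rules only classify predictions relative to a nearby
reference event; `evaluation_config(count_spurious_fp = TRUE)` switches to
the stricter reading in which every surplus prediction costs a false
positive.

MAE pools TPs and FPs (late-but-matched events carry real temporal error;
FNs carry none), with a 95% CI from a seeded nonparametric bootstrap
(2000 resamples; the CI construction is a package choice, switchable to
the normal approximation). Cumulative detection curves report, for
tolerance w = 0..4 frames, the fraction of all reference events matched
within w. Method comparison uses Shapiro-Wilk normality reporting as an
informational gate, a two-sided Wilcoxon signed-rank test in normal
approximation with tie correction (zero differences dropped, no continuity
correction), Bonferroni correction by the number of comparisons (3 for the
three-way method contrast), and effect size `r = |Z| / sqrt(N)` with `N`
the number of pairs.

## Splitting and the zero-shot protocol

`split_dataset()` assigns *subjects* (never trials) to train/validation/
test at 60/10/30 by default, independently per pathology class with
largest-remainder rounding, so one person's trials never straddle
partitions. Classes passed as `holdout_classes` go entirely to the test
set: the protocol for a pathology too small to train on, evaluated purely
zero-shot. `run_experiment()` wires the full pipeline — simulate, split,
train both detectors, fit heuristic thresholds, detect, evaluate, compare
— from a single seeded configuration and emits a versioned JSON/CSV
report; identical configurations reproduce reports byte for byte.

## Numerical and degenerate-input choices

* Constant feature channels normalize to 0.1 (the range rule's limit).
* `weighted_cross_entropy` clamps probabilities at 1e-12 before the log.
* A trial with zero walking speed has no detectable FO threshold; the
  heuristic returns an empty table flagged with a warning attribute.
* Event frames are 0-based integers at the trial's sampling rate;
  sub-frame reference times (e.g. 1500 Hz force plates) are rounded to
  the nearest camera frame, isolated in the C3D reader and
  `resample_trial()`.
* Resampling maps event times by nearest-frame rounding and linearly
  interpolates trajectories; it exists to study sampling-rate mismatch
  between laboratories (e.g. 100 Hz vs 150 Hz captures).
* Peak-detection plateau ties, matching ties and threshold-grid ties all
  resolve towards the lower frame / smaller threshold, so every stage is
  deterministic.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script exercise the pipeline at
desk scale, chosen as the smallest sizes at which the studied effects are
stable: heuristic recovery on 20 noise-free heel-strike trials of 12 s;
detector learnability on 200 mixed heel/forefoot trials (2 mm noise) with
a reduced model (one bi-directional layer of 32 units, ratio 1:10, 10
epochs); the zero-shot study on 75 trials from three profiles with the
drag profile held out (15 epochs). The reference clinical configuration
(3 x 200 units on thousands of trials) trains the same code path
unchanged, only longer.

## Known limitations

* The simulator's stylized kinematics make the learning task easier than
  clinical data; reported synthetic detection rates are upper bounds on
  clinical performance.
* The heuristic reconstruction ("modified Ghoussayni") resolves details
  the literature leaves unspecified; other laboratories' variants may
  differ in smoothing and gating.
* The C3D reader supports the common modern subset (Intel processor
  type, integer or float point data, POINT/EVENT groups); exotic DEC/MIPS
  files are rejected explicitly.
* Training is CPU-only and sequence-serial; it is sized for reduced
  configurations, not for grid searches over the full 252-point space on
  large cohorts.
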