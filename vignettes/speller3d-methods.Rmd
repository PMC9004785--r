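---
title: "Models and methods behind speller3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speller3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speller3d)
```

## The problem

A P300 speller lets a user type by attention alone. A 6×6 grid of 36
symbols is displayed and groups of symbols are intensified ("flashed") in
rapid succession; when the group containing the attended character
flashes, the brain produces a P300 — a positive EEG deflection peaking
roughly 300 ms after the stimulus. Detecting which column and which row
elicited P300s identifies the character.

`speller3d` implements two presentation paradigms end to end:

* **2D-RC** (classical row–column): the 6 columns and 6 rows flash in
  random order, 12 stimuli per trial, 15 trials per character (180
  flashes per run, stimulus codes 1–6 = columns, 7–12 = rows).
* **3D-C** (column-only with grid transposition): first the 6 columns
  flash 15 times each (90 flashes, codes 1–6); the grid is then
  transposed and re-displayed for 5 s, after which the former rows flash
  *as columns* (90 flashes, codes 7–12). The 3D-styled stimuli are
  modelled as a multiplicative P300 amplitude gain.

A session presents 60 characters (60 runs) with a 3-minute break after
every 15th run; breaks carry no events and generate no signal.

## Timing

Onset-to-onset spacing (SOA) is fixed at 175 ms: a 100 ms intensification
followed by a 75 ms inter-stimulus interval. The 3D animation's
background frames are rendered inside this envelope, i.e. they overlap
the ISI rather than extending it, so both paradigms share one event
clock. The target is displayed alone for 5 s before flashing starts, and
the 3D-C transposition pause is likewise 5 s. At the 250 Hz sampling
rate used throughout, onsets are rounded to the nearest sample when a
recording is synthesized.

Randomization is an independent uniform permutation per block of 12 (or
6, per phase, for 3D-C) stimulus codes. No adjacency constraint is
imposed across block boundaries — the same code may end one block and
begin the next. Every seeded generator draws its own substream, so equal
seeds give byte-identical schedules, recordings and reports.

## The synthetic EEG generator

No public recordings accompany the study this package models, so the
generator produces the statistical structure the downstream analysis
assumes, with every parameter explicit:

* **Background noise**: per-channel independent Gaussian noise with a
  1/f^β power spectrum (FFT-shaped, then standardized), β = 1 and
  SD = 10 µV by default. One exponent captures the low-frequency
  dominance of resting EEG without fitting an AR model.
* **P300 template**: a raised-cosine (Hann) bump — peak amplitude 5 µV
  at 300 ms latency, half-amplitude half-width 80 ms, identically zero
  beyond ±160 ms of the peak. Per-trial latency jitter is Gaussian with
  SD 25 ms. The compact support makes the noise-free injection exactly
  testable.
* **Topography**: the 11 analyzed electrodes (Cz, CP1, CP2, P7, P3, Pz,
  P4, P8, O1, Oz, O2) carry fixed spatial gains — P8 1.0, other parietal
  0.9, occipital 0.8, central 0.7 — so the best single electrode in the
  simulation is P8, mirroring the empirical finding the analysis is
  meant to reproduce.
* **Paradigm contrast**: under 3D-C every injected response is scaled by
  `paradigm_gain` (default 1.3), the one systematic difference between a
  subject's two sessions. Per-subject amplitudes are drawn uniformly
  from 4–6 µV to spread SNR across a cohort.
* **Overlap**: responses of consecutive flashes sum linearly. At the
  175 ms SOA a response (support ≈ 140–460 ms post onset) bleeds into
  the next one or two epochs; this is deliberate and realistic. It also
  means the "non-target averaged epochs are exactly zero" property holds
  only when the SOA exceeds the template support, which is how the
  exactness tests are constructed (SOA 1200 ms); at 175 ms the classes
  remain perfectly separable noise-free, which is what the
  100 %-accuracy checks assert.

The generator does **not** model blinks, muscle or line-noise artifacts,
volume conduction, electrode drift, or re-referencing (signals are
already referenced). Passing tests therefore demonstrate correctness of
the pipeline's arithmetic and its statistical behaviour under the stated
assumptions — not performance on real recordings.

## Preprocessing

1. **Band-pass 0.1–10 Hz**: 4th-order Butterworth applied
   forward–backward (zero phase) per channel, realized as
   `signal::butter(2, c(0.1, 10)/125)` + `filtfilt`. The original
   description names only the band; order and phase handling are package
   choices, and the zero-phase variant is preferred because epoch
   latencies feed the template comparison directly.
2. **Epoching**: −200 ms to +1000 ms around each flash onset — 50
   pre-stimulus plus 250 post-stimulus samples. The onset sample is the
   first post-stimulus sample; the pre-stimulus window is half-open at 0.
3. **Baseline correction**: the scalar mean of the 50 pre-stimulus
   samples is subtracted per channel from the entire epoch. Correcting
   twice is a state error.
4. **Repetition averaging**: within each run the first *n* ∈ {1, 3, 15}
   presentations of each code, in presentation order, are averaged and
   cropped to the post-stimulus second, giving 12 averaged responses per
   run. "First *n*" is a deterministic choice; the original study does
   not say which subset its reduced-flashing analyses used. Averaging
   always precedes train/test splitting.

## P300 detection

Features are the selected channels' averaged post-stimulus signals
concatenated (d = 250 per channel, 2750 for the full 11-electrode set).
Concatenation preserves spatial structure and reduces to the stated
d = 250 in the single-channel case; the original description never
states a fusion rule. Labels: 1 iff the epoch's code is one of the run
target's two codes — 2 positives and 10 negatives per run. No class
re-weighting is applied; the noise-free limit is separable, so accuracy
remains interpretable.

The detector is a two-layer network: d inputs, M = 50 tan-sigmoid
(tanh) hidden units, one output. The original formulation declares the
output unit linear while training with a cross-entropy loss that needs
probabilities in (0, 1); the package resolves this the standard way — a
logistic squashing on the linear output for both the loss and the 0.5
decision threshold. The loss is the mean binary cross-entropy with
scores clipped at 10⁻¹², and its gradients are derived analytically
(verified against numerical differentiation to 10⁻⁶ relative).

Training is deterministic full-batch gradient descent with momentum 0.9
and a "bold driver" step-size rule: the step grows 5 % after an epoch
that does not worsen the training loss and is halved (with the step
undone and momentum reset) otherwise, starting at 0.5. Weights start
uniform in ±1/√fan-in under a seed. Early stopping monitors the
validation loss with patience 25 (cap 500 epochs) and the best-validation
weights are returned. Any deterministic first-order scheme satisfies the
contract; this one needs no per-dataset tuning.

Evaluation repeats 20× by default: a fresh stratified 70/15/15
train/validation/test split (stratification keeps the 2:10 class ratio
equal across splits to within a sample), fresh initialization, training,
and the test accuracy at threshold 0.5; the mean and SD over repeats are
reported.

## Character decoding

Per run the 12 averaged epochs are scored by the trained detector;
predicted column = argmax over codes 1–6, predicted row = argmax over
codes 7–12, ties toward the lowest code, and the character is the grid
cell at that row and column. Argmax (rather than thresholded detection)
guarantees a unique prediction and is invariant to monotone score
transforms.

Character recognition uses the 3-fold protocol: the 60 runs are
shuffled under a seed into three folds of 20; each fold in turn is the
*training* set (its 240 feature vectors, with an internal stratified
train/validation split for early stopping) and the other 40 runs are
decoded. Counts correct out of 40 are reported per fold and averaged.
The detector is retrained from scratch per fold; no information crosses
the partition.

## Metrics

* **Accuracy** is (TP+TN)/(TP+TN+FP+FN).
* **ACRC** (area covered by the radar curve) summarizes the 15
  accuracies (11 electrodes then Groups 1–4, in that fixed order) as the
  normalized area of the radar polygon:
  Σᵢ 0.5·CAᵢ·CAᵢ₊₁·sin 24° with cyclic closure CA₁₆ = CA₁, divided by
  the all-ones maximum 15·0.5·sin 24°. Closure is required because the
  printed sum leaves CA_{N+1} undefined and a radar polygon is closed;
  normalization is required because the statistic is described as lying
  in [0, 1]. Accuracies enter as fractions, so a constant profile c
  yields exactly c². The label order is part of the metric's contract:
  ACRC is invariant under rotation but not under arbitrary permutation.
* **Significance**: although described as a "two-sample" test, the
  stated 9 degrees of freedom with 10 subjects per condition force the
  paired reading; the package computes the paired two-tailed t test on
  per-subject differences, flagged at α = 0.05 and 0.01. Identical
  vectors return t = 0, p = 1; non-identical vectors with zero-variance
  differences are a degenerate-test error.

## Embedded reference summaries

The published per-subject tables (ACRC, P8 accuracy, Group-4 accuracy,
character counts) are embedded as literal data so the aggregation
arithmetic is verifiable offline. `verify_reference_tables()` recomputes
every mean row from the per-subject values and every improvement
percentage from the printed means, and reports deltas. Three published
Group-4 cells disagree with their own per-subject columns by 0.01–0.02
accuracy points, the published Group-4 improvements 4.36 %/1.01 % are
not exactly derivable from the printed means (which give 4.37 %/1.02 %),
and the published 3D-C 1-flashing character percentage 69.4 % conflicts
with its own counts (27.4/40 = 68.5 %); the embedded counts are treated
as authoritative and the deltas are exposed rather than hidden.

## Problem sizes and numerical choices

The full protocol (10 subjects × 2 paradigms × 60 characters × 15
electrode sets × 3 flashing counts × 20 repeats) is supported by
`run_study()` but is deliberately not what the test suite runs. The
shipped checks use sizes chosen to measure each property precisely while
keeping the suite fast: noise-free perfection is asserted on a full
60-run session per paradigm at 1/3/15 flashings for P8 and Group 4;
flashing-count monotonicity on 5 seeded 12-character cohorts with
10-repeat evaluation; the paradigm ACRC contrast on 10 seeded
24-character single-trial cohorts over all 15 electrode sets with
2-repeat evaluation; the
1/√n averaging law on 1000 simulated runs; uniformity of the block
randomization on 10 000 seeded schedules.

Other numerical details: accuracies are reported in percent with means
rounded to 2 decimals only at the reporting layer; schedule onsets are
kept in ms and rounded to samples only at synthesis; `which.max`
implements the lowest-code tie-break; filtering near the 0.1 Hz edge is
stable because the design is order 2 per band edge applied twice
(forward/backward).

## Known limitations

* Synthetic EEG only; the published subject-level accuracies (e.g.
  99.81 % detection) depend on unavailable recordings and are **not**
  reproduced — only the aggregation arithmetic over the published
  per-subject values is.
* The noise model has no artifacts or channel covariance, so group
  electrode sets gain less from spatial pooling than real data would
  show.
* The optimizer is plain first-order descent; MATLAB-era training
  (likely scaled conjugate gradient) would converge differently, though
  any minimizer of the same loss satisfies the same invariants.
* Real-data ingestion is limited to the generic channels×samples +
  marker-table containers; no vendor EEG formats are read.
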