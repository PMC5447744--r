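---
title: "Single-trial P300 detection with stacked sparse autoencoders: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial P300 detection with stacked sparse autoencoders: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

The P300 is a positive event-related potential (ERP) peaking roughly
300–500 ms after a rare, attended stimulus in an oddball paradigm. Detecting
it in a *single* trial — without averaging dozens of epochs — is what makes
P300 brain–computer interfaces responsive, and it is hard because the
component (a few microvolts) is buried in ongoing EEG of comparable or larger
amplitude. `p300sae` implements a complete single-trial detection pipeline:

1. a synthetic oddball-EEG generator (so every stage is testable without any
   external recording),
2. marker-locked epoching and balanced trial-set assembly for a
   cross-subject train/test design,
3. windowed-means feature extraction,
4. a from-scratch stacked sparse autoencoder (SAE) classifier with an MLP
   and a shrinkage-LDA baseline, and
5. an evaluation layer (accuracy/precision/recall, McNemar paired tests).

The design target throughout is the cross-subject setting: classifiers are
trained once on a pooled multi-subject training set and then applied to
held-out subjects with no further weight updates.

## The simulator

`simulate_session()` emulates a three-stimulus oddball recording: 19
channels (10–20 montage) at 1 kHz, one stimulus per second with
non-target/target/distractor probabilities 0.83/0.135/0.035, three phases
that each run until 30 target stimuli have occurred (so a session always
carries 90 targets), and marker codes `"S  2"` (target) / `"S  4"`
(non-target) in the stimulus track.

The continuous signal is a superposition of three parts:

* **Background** (`generate_background()`): per channel, 1/f ("pink") noise
  generated by spectral shaping (power ∝ 1/f^α, default α = 1, SD 4 µV),
  an alpha-band sinusoid (10 Hz, 4 µV, random per-channel phase), and white
  Gaussian noise (SD 2 µV). These defaults give a background SD of roughly
  5 µV, so a 2–10 µV P300 is genuinely hidden at the single-trial level —
  the regime the classifiers are meant to handle.
* **Target responses** (`generate_event_response()`): a Gaussian bump in
  time, peak amplitude A at the maximum-gain channel, mean latency 400 ms
  with configurable trial-to-trial jitter (default SD 30 ms) and temporal
  spread (Gaussian SD, default 60 ms). The bump is scaled per channel by a
  fixed centro-parietal topography peaking at Pz. A Gaussian kernel was
  chosen because it is smooth, unimodal, and controlled by exactly the two
  parameters that matter scientifically (latency, width).
* **Distractor responses**: off by default; distractor markers still occur
  so the "ignored during processing" path is always exercised. A profile
  may define a frontal, earlier P3a analogue.

All randomness flows through explicit integer seeds; per-subject and
per-stage sub-streams are derived deterministically from one master seed, so
a session with amplitude 0 shares its background and marker track
sample-for-sample with the same-seed session at any amplitude. This
superposition property is tested directly.

What the simulator does *not* model: biophysical head volume conduction,
eye-blink/EMG artifacts, electrode drift, non-stationary alpha power, or
inter-channel noise correlation. Passing recovery tests on this generator
therefore shows that the pipeline's statistics and learning machinery work,
not that the reported real-data performance level would be reproduced on
arbitrary clinical recordings.

## Epoching and trial sets

Epochs span the half-open window [−500, +1000) ms around each marker —
exactly 1500 samples at 1 kHz with stimulus onset at sample offset 500. The
window is half-open so the sample count is exact; trials that would overrun
a recording edge are dropped and counted rather than zero-padded. Marker
codes are compared after whitespace normalization because BrainVision
writers differ in padding (`"S 2"` vs `"S  2"`).

Two assembly rules implement the cross-subject design:

* **Training** (`assemble_training_set()`): per training subject, all target
  trials plus an equal-count uniform random subset of that subject's
  non-targets; the pooled set is then shuffled. The result is exactly
  class-balanced.
* **Testing** (`select_test_trials()`): per test subject, all targets plus
  the chronologically *first* equal number of non-targets, preserving trial
  order.

`split_validation()` provides the 20% random validation split used for
model selection (732 rows split 586/146).

## Features

`baseline_correct()` subtracts the mean of the 500 ms pre-stimulus window
per trial and channel. `windowed_means()` averages each channel over eleven
half-open 50 ms windows between 150 and 700 ms post-stimulus and
concatenates channel-major — 11 × 19 = 209 features. Window edges map to
samples by `floor(t · fs / 1000)`, so each window holds exactly 50 samples
at 1 kHz. `normalize_rows()` scales every feature vector to unit Euclidean
norm ("length" normalization); the unit sphere suits both the LDA geometry
and sigmoid networks. The concatenation order is recorded in
`feature_names` (`"Pz:350"` = channel Pz, window starting 350 ms) so the
layout is auditable.

## The stacked sparse autoencoder

A single autoencoder approximates the identity in two stages,
x̂ = f_dec(f_enc(x)) ≈ x, with logistic-sigmoid encoder and decoder and an
encoding narrower than the input. The training objective per batch of n
rows is

cost = (1/n) Σ‖x − x̂‖² + (λ/2)(‖W_enc‖² + ‖W_dec‖²) + β Σ_j KL(ρ ‖ ρ̂_j),

with KL(ρ‖r) = ρ log(ρ/r) + (1−ρ) log((1−ρ)/(1−r)) and ρ̂_j the batch-mean
activation of hidden unit j. Defaults: λ = 0.004, β = 4, ρ = 0.2, at most
200 epochs per autoencoder. Biases are excluded from the weight penalty;
ρ̂ is clamped to [10⁻⁶, 1−10⁻⁶] (with a warning) to keep the KL term
finite. The analytic gradients are verified against central finite
differences to below 10⁻⁶ relative error — this is the module's core
oracle and runs in the test suite.

The full classifier (`train_sae()`) works in four steps:

1. **Input scaling.** Each feature column is affinely mapped onto
   [0.1, 0.9] (constant columns to 0.5) and the map is stored in the model
   for inference. A sigmoid decoder cannot reproduce values outside (0, 1),
   so unit-norm real features must be brought into its range.
2. **Greedy pretraining** (`train_stack()`): autoencoders of sizes
   130, 100, 50, 20 are trained one at a time, each on the encoding of the
   data through the layers before it.
3. **Softmax head** (`train_softmax()`): cross-entropy training (200
   iterations) on the 20-dimensional code.
4. **Fine-tuning** (`fine_tune()`): joint cross-entropy backpropagation
   through all layers. Regularization is applied during pretraining only;
   fine-tuning minimizes the plain cross-entropy. The default is 200
   iterations; the count is configurable because it is a tuning choice
   rather than a protocol constant.

The default architecture string is exactly `209-130-100-50-20-2`. Decoder
weights are untied from encoder weights.

**Optimizer.** All three training stages share one deterministic full-batch
optimizer: gradient descent with momentum (step 0.1, momentum 0.9), where a
step is accepted only if the cost does not increase; otherwise the step size
is halved and the velocity reset. This makes every trained cost trace
monotone non-increasing, makes training exactly reproducible from a seed,
and keeps the whole procedure auditable — properties worth more here than
raw convergence speed. Weights initialize uniformly in
±√(6/(fan_in+fan_out)), seeded.

## Baselines

* **MLP** (`train_mlp()`): identical layer sizes, transfer functions, input
  scaling and forward-pass code to the SAE (a parameter-transplant test
  enforces this), but randomly initialized and trained by joint
  backpropagation only, default 1000 iterations. Any SAE-vs-MLP difference
  is therefore attributable to pretraining, not implementation details.
* **Shrinkage LDA** (`train_shrinkage_lda()`): pooled within-class
  covariance shrunk toward ν·I (ν = average eigenvalue) with the analytic
  Ledoit–Wolf/Schäfer–Strimmer intensity, w = Σ⁻¹(μ₁ − μ₀), threshold at
  the projected class-mean midpoint (appropriate because both trial sets
  are balanced by construction). At intensity 0 it reproduces classical
  LDA exactly; at 1 the decision direction is the class-mean difference.
  Points exactly on the boundary classify as non-target.

## Evaluation

With target as the positive class: accuracy = (tp+tn)/(tp+tn+fp+fn),
precision = tp/(tp+fp), recall = tp/(tp+fn), reported in percent; a metric
with a zero denominator is reported as `NA` with a warning.
`mcnemar_compare()` counts discordant trials between two classifiers and
uses the exact two-sided binomial test below 25 discordant pairs and the
continuity-corrected chi-square above (the switch point is standard practice
and config-exposed). `run_study()` ties everything together and pools the
test trials of all subjects for the McNemar comparisons; a per-subject
variant can be computed from the stored predictions.

## Numerical and design choices

* Epoch windows and feature windows are half-open; boundary samples belong
  to the later window. Ties in network probabilities (exactly 0.5/0.5)
  classify as non-target; the same convention holds for the LDA boundary.
* The monotone optimizer guarantees final cost ≤ initial cost for every
  stage, which the tests assert.
* The internal single-file container uses R native serialization with a
  format sentinel; round-trips are bit-exact. BrainVision support reads the
  multiplexed INT_16 (scaled by the per-channel resolution) and
  IEEE_FLOAT_32 dialects and writes a minimal triplet for fixtures and
  interchange; other layouts raise explicit unsupported-dialect errors.
* Degenerate inputs fail loudly: all-zero feature rows name the offending
  trial, single-class training data, unbalanced-able trial sets, and
  overlapping train/test subject lists are all explicit errors.

## Problem sizes in the shipped runs

The packaged tests exercise full-scale sessions (3 × 30 targets, 19
channels, 1 kHz) where the protocol's structure is the point, and reduced
sessions (one phase, 3–10 targets) where only the mechanics matter. The
recovery checks run the complete study design — 4 training + 11 testing
subjects at full session length — once with a strong (10 µV, low-noise)
P300 to verify near-ceiling SAE recovery, and once with amplitude 0 to
verify chance-level behavior; these sizes keep the whole suite at a few
minutes on one core while still running the genuine end-to-end design. The
analysis scripts under `analysis/` run the same design at the realistic
default noise and amplitude ranges.

## Known limitations

* The simulator's stationarity and channel independence make the synthetic
  task easier than real cross-subject transfer; absolute accuracies on
  synthetic cohorts are not comparable to real-data results.
* The pipeline supports loading real BrainVision recordings
  (`read_brainvision()`, or `recording_files` in a study config) for the
  documented manual workflow, but no automated test depends on external
  data.
* Full-batch training is deliberate (determinism, monotonicity); for much
  larger training sets a stochastic optimizer would be the natural
  extension.
* Only the two-class target/non-target decision is implemented; distractor
  epochs are never extracted.
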