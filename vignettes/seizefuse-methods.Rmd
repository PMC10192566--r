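---
title: "Multimodal seizure prediction with episode-adversarial training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal seizure prediction with episode-adversarial training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Seizure prediction asks whether the minutes immediately before a seizure
(the *preictal* state) can be distinguished from the seizure-free baseline
(the *interictal* state) in scalp recordings. `seizefuse` implements a
patient-specific predictor that classifies every 1-second window of a
recording as preictal or interictal, using two modalities at once — the
multichannel EEG and the simultaneously recorded single-channel ECG — and
that explicitly addresses the fact that *each seizure episode of the same
patient looks different*: physiological state, electrode placement and
vigilance drift between episodes, so a classifier that keys on
episode-specific quirks of its training seizures transfers poorly to the
next one.

Three ideas are combined:

1. **Two independent modality branches.** EEG windows are read by a
   bidirectional LSTM (one 29- or 8-dimensional channel vector per time
   step) followed by four 1-D convolution blocks; ECG windows are first
   turned into a Mexican-hat continuous-wavelet scalogram (32 scales) and
   read by five 2-D convolution blocks. Each branch ends in a two-layer
   fully connected classifier head that emits class probabilities.
2. **Decision-level fusion with dynamic error-rate weights.** The fused
   probability is `W1 * p_eeg + W2 * p_ecg` with unnormalized weights
   `w = 1 + arctan((1 - err) / err)` computed from each branch's
   validation error rate and normalized to `W1 + W2 = 1`. The more
   reliable branch dominates; the weaker branch still contributes. Fixed
   equal weights (`0.5/0.5`), a jointly learned softmax weighting, and
   data-level (stacking the ECG trace under the EEG montage) and
   feature-level (concatenating branch features) fusion are available as
   ablation modes.
3. **Episode-adversarial training.** Each branch's feature extractor feeds
   an *episode discriminator* — a softmax head over the training episodes
   of the current fold — through a gradient reversal layer (GRL): identity
   in the forward pass, gradient times −1 in the backward pass. The joint
   objective is `L_sum = L_c − λ (L_d_eeg + L_d_ecg)` with `λ = 0.1`; the
   discriminators descend their cross-entropy while the extractors receive
   the reversed, λ-scaled gradient, driving features whose distribution is
   the same in every episode. Setting `λ = 0` removes the adversarial term
   entirely and is the non-adversarial ablation.

Evaluation is leave-one-episode-out: per patient, each episode serves once
as the test set while all others train the model; a patient needs at least
three episodes, otherwise every fold would train on a single episode and
overfit it. Reported metrics are per-window accuracy, sensitivity,
specificity and the false alarm rate FAR = `N_alarm / N_wo` (alarmed
interictal windows over all interictal windows), aggregated across folds
both as mean ± sd and from the pooled confusion table.

Two specificity conventions exist in the literature this package follows:
the standard `TN / (TN + FP)` (the default) and an "as-printed" variant
`TN / (TP + TN)` that some accounts of this method state verbatim — almost certainly a
typo, but reproducible here via
`classification_metrics(..., sp_definition = "as-printed")`.

## Preprocessing

The pipeline order is fixed: filter → normalize → segment → (ECG only)
scalogram.

* **Filtering** is zero-phase (forward–backward `filtfilt`) so that labels
  keep their timing relative to the signal: an order-4 Butterworth
  high-pass at 0.1 Hz cascaded with an order-4 low-pass at 70 Hz, then an
  order-2 band-stop at 48–52 Hz for mains interference. The band-pass is
  realized as a high-pass/low-pass cascade because a single
  transfer-function band-pass with a 0.1 Hz lower edge is numerically
  fragile at 512 Hz. `filter_signal()` refuses sampling rates at or below
  twice the low-pass corner; configurations with lower rates must lower
  the corner (the run-configuration layer does this automatically when the
  cutoffs are left unset).
* **Normalization** is min–max to `[0, 1]`, applied per channel per
  recording (episode scope), after filtering. The scope matters: any wider
  scope would let statistics of a held-out episode leak into training
  folds. A constant channel maps to zeros with a warning.
* **Segmentation** tiles every state interval with 1-second windows at 0%
  overlap (both configurable); a trailing partial window is dropped, never
  padded. Window counts are therefore exactly
  `floor(interval_samples / window_samples)` per interval.
* **Scalograms** use the Mexican-hat mother wavelet at integer scales
  1..32 with the `1/sqrt(a)` normalization, signed coefficients (no
  modulus), and time in sample units; the signal is treated as zero
  outside the window. The time axis is average-pooled by a factor of 4
  before the 2-D network to bound memory; the factor is a configuration
  knob.

## Training procedure

Defaults mirror the method's standard recipe: Adam at learning rate 0.001, batch
size 128, 100 epochs, `λ = 0.1`; an optional center loss (weight 0.01,
its own SGD at learning rate 0.05, off by default so the default objective
is exactly `L_sum`). Per fold, a stratified validation split
(20% of training segments, stratified by class × episode) estimates the
branch error rates after every epoch; fusion weights are recomputed each
epoch and the model state and weights finally used are those of the epoch
with the lowest validation fused error. Episode labels for the
discriminators are the training episodes of the fold, relabeled `0..K−1`;
the held-out episode has no discriminator class. One global seed expands
deterministically into per-fold seeds, and runs are exactly reproducible.

Three training details were settled empirically on the synthetic study
conditions and are worth recording because each one was load-bearing:

* **Input centering.** Min–max-normalized windows have mean ≈ 0.5;
  feeding them to the Bi-LSTM uncentered left the gates near saturation
  and training frequently never escaped chance. The EEG branch therefore
  subtracts 0.5 on entry.
* **Feature batch normalization.** Without any normalization in the
  network, the feature extractor can "win" the adversarial game
  degenerately, by inflating feature norms (which blows up the
  discriminator's cross-entropy while sharpening its own classifier
  logits). A batch-normalization layer at each extractor's output removes
  that direction; it is also what makes marginal feature alignment across
  episodes meaningful.
* **Adversarial schedule and discriminator refinement.** The adversarial
  weight ramps from 0 to λ over training (the usual GRL schedule), so the
  class signal is acquired before invariance pressure applies. Each
  mini-batch performs the shared GRL backward pass and then
  `disc_steps − 1` (default 4) extra discriminator-only updates on the
  same frozen features. With a single shared pass the discriminators lag
  the features and the reversed gradient chases a stale boundary — the
  features *hide* episode information from the current discriminator
  rather than discarding it (a fresh probe recovers it); refreshed
  discriminators make the reversed gradient track a near-optimal
  adversary. This deliberately extends the single-backward-pass GRL idiom,
  keeping the joint objective unchanged.

## The synthetic study conditions

The generator (`synthetic_spec()` / `generate_patient()`) produces the
statistical structure the method assumes, not physiological realism: no
ictal morphology, no artifacts, no wake/sleep cycles. Its defaults are the
package's study conditions, chosen once so that a single CPU core trains a
fold in seconds: 3 episodes, 60 s of interictal plus 60 s of preictal per
episode, 64 Hz, 8 EEG channels (the full-scale setting — 512 Hz, 29
channels, ≥5-minute blocks — remains reachable through the same fields).
At 64 Hz the Nyquist range still contains all the spectral structure the
method needs.

Per episode the EEG is band-limited Gaussian noise plus a shared 16 Hz
background rhythm whose amplitude drifts mildly across episodes
(`1 + 0.15 · episode_shift · e`). The preictal signature has two parts:

* an **episode-stable** narrow-band 5 Hz component with amplitude
  `eeg_effect`, spread over all channels — the reliable marker an
  episode-invariant model should use;
* an **episode-bound** rhythm (amplitude `2.5 · eeg_effect ·
  min(1, episode_shift)`, two channels) whose centre frequency moves with
  the episode (8, 10, 12 Hz at `episode_shift = 1`) and whose class
  association flips: it accompanies preictal spans in all but the last
  episode, where it occurs during the interictal baseline instead.

This is a concrete, controllable instance of "every episode expresses the
preictal state differently". The frequency signature makes the
episode-bound rhythm strongly episode-discriminative — it survives
per-channel min–max normalization, which erases amplitude-based markers —
so invariance pressure suppresses it; a non-adversarial model may treat it
as a preictal marker (it is consistent across its training episodes) and
misread the one episode where the association flips. Both components scale
with `eeg_effect`, and the episode-bound one also with `episode_shift`, so
zero-effect data is exactly class-null and zero-shift data is exactly
episode-exchangeable.

The ECG is a Gaussian-bump pulse train (bump width 40 ms) whose mean
inter-beat interval (0.8 s, drifting 5% per episode step with
`episode_shift`) shortens during preictal spans by the factor
`1 − 0.2 · ecg_effect` (floored at 0.35), with multiplicative jitter
scaled by `noise_sd` — the preictal heart-rate acceleration that motivates
using ECG at all, expressed in the scalogram as denser bump spacing.

Effect sizes were calibrated once, on held-out-episode accuracy of the
single branches across a grid (recorded in
`inst/extdata/calibration-synthetic.json`), and then frozen: the defaults
`eeg_effect = 0.8`, `ecg_effect = 0.8`, `episode_shift = 1` give a patient
on which each branch is clearly better than chance but imperfect, the
episodes shift visibly, and adversarial training has something real to
fix; `eeg_effect` or `ecg_effect` around 2–3 at `episode_shift = 0` gives
single-branch accuracy ≥ 0.95 (the easy regime), and both effects at 0
give chance.

What passing tests on this generator do **not** show: robustness to
artifacts, montage differences, class imbalance (real interictal data
vastly outnumbers preictal), seizure-onset annotation error, or any
clinical endpoint. They show that the pipeline's machinery — filtering,
scalograms, both branches, fusion, the adversarial objective and the
evaluation protocol — does what it claims on data whose ground truth is
known exactly.

## Scaled-down experiment sizes

All in-package experiments (tests and the acceptance script) use the
compact configuration `compact_branch_config()` /
`compact_train_config()`: LSTM hidden size 8, 1-D conv channels
(8, 8, 16, 16), 2-D conv channels (4, 4, 8, 8, 16), feature dimension 16,
heads of width 16, 20 epochs, batch size 16, Adam at 0.003 — about 7,000
trainable parameters across both branches. These sizes are the package's
own choice of study scale; the full-scale widths (`branch_config()`
defaults) train the same code path. The feature dimension is kept small
deliberately: a 16-dimensional feature space leaves the extractor little
room to hide episode information from the discriminators, which is what
makes marginal alignment effective at this scale.

The adversarial comparison (λ = 0.1 vs λ = 0, ten seeds, paired one-sided
t-test) and the probe-discriminator check (a freshly trained multinomial
classifier on frozen features must stay near episode-chance after
adversarial training, but not after control training) run at exactly these
conditions in `tests/testthat/test-acceptance.R`.

## Numerical choices and degenerate inputs

* Min–max of a constant input returns zeros with a warning.
* Error rates below `1e-6` are clamped before the arctangent, keeping
  weights finite and order-preserving (`arctan(∞) = π/2`).
* A fused probability tie predicts class 0 (interictal) — the
  conservative, no-alarm choice.
* Metrics with a zero denominator are `NA` ("undefined"), never silently 0.
* Max-pool ties take the first element; trailing odd elements are dropped
  in 1-D pooling, and 2-D pooling skips an axis that has reached size 1.
* Cross-entropy probabilities are floored at `1e-12` inside the logarithm;
  gradients flow through the exact softmax Jacobian, so the composite
  gradient stays bounded.
* The EDF writer re-reads its own printed physical-range header fields
  when scaling samples, so a round trip is exact up to 16-bit
  quantization.
* All layer backward passes are verified against central finite
  differences in the test suite (the engine is hand-written; there is no
  autograd to trust).

## Design choices on genuinely open points

* **Error rates from a validation split.** Whether the fusion error rates
  come from training or held-out data, and whether weights freeze or
  update per epoch, is underdetermined in the method's public description
  (the weighted-average equation is even annotated as "learnable"). This
  implementation computes them on the 20% validation split at every epoch
  and uses the best-validation epoch's weights; a jointly learned softmax
  weighting is available as `weights = "learned"` for comparison.
* **Interictal selection on real recordings.** How far interictal data
  must stay from seizures is not specified anywhere; the EDF layer uses a
  configurable guard gap (default 30 min before onset and after offset)
  and discards interictal spans shorter than 5 min. The synthetic
  generator sidesteps the question by construction.
* **Discriminator optimizer.** The discriminators reuse the main Adam
  optimizer (their own learning rate is unstated in the source method);
  the λ-scaling of their gradient is immaterial under Adam's
  scale-adaptive updates.
* **Center loss attachment.** The center loss appears only in the
  training recipe of the source method, not in its loss equations; it is
  implemented on each branch's feature output with weight 0.01 and its
  prescribed SGD(0.05), but disabled by default so that the default
  objective is exactly `L_sum`.

## Known limitations

* The hand-written engine is CPU-bound R; the full-scale widths at
  512 Hz/29 channels train, but slowly — the package is a faithful,
  testable implementation of the method, not a GPU training framework.
* Exact layer-level hyperparameters of the method's original model are
  not public, so its absolute headline numbers cannot be reproduced
  bit-for-bit; all
  in-package claims are therefore property-based (directions, bounds,
  protocol identities) on synthetic data.
* Real-data use requires EDF files whose channels have a uniform sampling
  rate; EDF+ embedded annotations are not parsed (seizure times come from
  a JSON/CSV sidecar).
* Single-window alarms: no persistence rule (k-of-n) is applied before
  declaring a false alarm, matching the per-window FAR definition.
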