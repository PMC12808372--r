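---
title: "Models and methods behind midecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind midecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`midecode` is a framework for *subject-independent* motor-imagery EEG
decoding: a synthetic data generator, a deterministic preprocessing
pipeline, a hybrid deep network family with transfer-learning
fine-tuning, a leave-one-subject-out (LOSO) evaluation engine, and
shallow comparators. This vignette explains the models, the assumptions
behind them, and the design decisions that were genuinely open.

## The synthetic ERD generator

Motor imagery suppresses the mu (8–12 Hz) and beta (13–30 Hz) rhythms
over the contralateral sensorimotor cortex (event-related
desynchronization, ERD). The generator emulates exactly the statistical
structure a band-power decoder exploits, and nothing more:

* **Background**: 1/f^α Gaussian noise per channel (default α = 1, RMS
  10 µV), produced by spectral shaping in the frequency domain. The
  log–log PSD slope of generated background recovers −α within ±0.3 over
  1–100 Hz.
* **Rhythms**: band-limited noise rather than sinusoids — white noise
  band-passed into 8–12 and 13–30 Hz. A sinusoidal rhythm would leak
  phase cues that no real ERD paradigm offers; with band-limited noise,
  class information exists *only* as a band-power change, which is the
  physiologically honest contract. Each band is scaled so the combined
  rhythm RMS equals `snr` × background RMS.
* **Lateralization**: each class attenuates the rhythm on its assigned
  channel by `1 − erd_depth`, only for t ≥ 0 (the cue); the 0.5 s
  pre-cue interval stays at baseline, matching cue-locked ERD
  physiology. The class→channel map is round-robin over the motor
  channels (for the 3-channel C3/Cz/C4 montage: class 0 → C3, class
  1 → C4) and is configurable.
* **Subjects**: one multiplicative gain per subject, drawn log-normal
  with σ = `subject_gain_sd` (log-normal keeps gains strictly positive).
  This reproduces the amplitude heterogeneity that makes
  subject-independent decoding hard, but not waveform-level
  idiosyncrasies.
* **Artifacts**: a configurable fraction of trials receives a half-sine
  EOG deflection of 0.5 s with a controlled peak amplitude (default
  150 µV — comfortably above the ±100 µV rejection threshold). The
  deflection's sign is matched to the underlying trace at its peak so
  the resulting peak provably reaches the requested amplitude, which
  makes the rejection threshold testable without tolerance games.

Defaults (`erd_depth = 0.5`, `snr = 1.5`, `subject_gain_sd = 0.2`,
`artifact_fraction = 0.05`) are fixed, realistic operating conditions: a
moderate ERD on a clearly visible rhythm, with subject variability large
enough to matter but not to swamp the class contrast. What the generator
deliberately does **not** model: volume conduction and channel
correlation, non-stationary drifts, EMG, or session effects. Tests that
pass on this data therefore certify the *pipeline* — contracts, leakage
discipline, learnability — not clinical-grade performance on real EEG.

## Preprocessing

The pipeline order is fixed and logged: common-average reference →
epoching → EOG rejection → band-pass → split → standardize.

* **Epochs** are half-open sample windows `[cue + round(start·fs), cue +
  round(end·fs))` with 0-based cue indices; at 250 Hz the canonical
  −0.5…4 s window gives 1125 samples. Cues whose window leaves the
  recording are reported and skipped, never silently dropped.
* **EOG rejection** uses a strict inequality (a trial peaking at exactly
  100 µV is retained): "exceeding" the threshold is read literally. It
  runs before filtering, because filtering would smear a blink across
  the epoch and hide its peak.
* **Band-pass**: 8–30 Hz, fourth-order Butterworth prototype, zero
  phase. The zero-phase pass is realized in the frequency domain as
  multiplication by |H(e^{jω})|² after symmetric reflect padding of
  3·(order+1) samples per side. This is the exact transfer function of
  an (infinite-length) forward–backward pass and makes time-reversal
  equivariance hold to machine precision, which a finite causal
  two-pass realization only approximates at the epoch edges. The price
  is a circular boundary handled by the reflect padding; the
  steady-state response is identical.
* **Standardization** is per channel, pooling trials × samples within
  one subject, fitted on the training portion only and applied frozen to
  validation and test. The pooling axis is a design choice (the
  convention is not universal): per-channel pooling preserves relative
  temporal structure within a trial, which the temporal convolutions
  consume. Constant channels fall back to a small floor with a warning.
* **Splits** are per-subject and stratified. Counts use
  round-half-to-even, then per-class quotas are repaired by
  largest-remainder apportionment, making the split deterministic,
  exhaustive and proportional within one trial per class. The two
  schemes are 20 % test / 25 % of the remainder for validation
  ("IV-2a") and 15 % / 18 % ("IV-2b"). Subject-wise splitting and the
  LOSO protocol coexist as two explicit evaluation modes.

## The network family

Input is a batch of trials, channels × samples. Two parallel branches
extract complementary features:

* **Deep branch**: two blocks of temporal 2-D convolution → batch-norm →
  activation → temporal max-pool (stride 2) → dropout 0.4. The first
  convolution spans all channels (kernel k_t × n_channels, valid in
  space), collapsing the spatial axis so the branch emits
  `(batch, 64, T′, 1)`; kernel lengths 7 and 5 come from the small-kernel
  menu {3, 5, 7}.
* **Shallow branch**: a spatial convolution over all channels (80
  filters), a temporal convolution (kernel 25), batch-norm + activation,
  temporal average-pool (stride 4), dropout 0.4. The normalization and
  activation after the temporal convolution are this package's addition
  (minimal recipes for this branch list only the four stages); without
  them the branch trains poorly next to its normalized sibling.

Both branches downsample time by the shared factor 4 (two stride-2
max-pools equal one stride-4 pool for every length, since
⌊⌊L/2⌋/2⌋ = ⌊L/4⌋), so their outputs concatenate to 144 features. A
kernel-1 convolution fuses them to a 128-dimensional sequence; fixed
sinusoidal positional encoding (parameter-free — the module is named but
unspecified, so the standard non-learned choice) precedes an 8-layer
post-norm transformer encoder (d = 128, 4 heads, GELU feed-forward of
width 2·d — the feed-forward width is unstated anywhere, and 2·d keeps
the model in the lightweight regime it is designed to occupy). A
3-layer bidirectional LSTM (128 units per direction, dropout 0.3)
refines the sequence; its output is mean-pooled over time and classified
by an MLP (hidden 128, dropout 0.5).

The simplified from-scratch variant reduces to 6 transformer layers and
2 BiLSTM layers and disables positional encoding. The `+LSTM` variant's
wiring is unspecified in prose; here it is a parallel *unidirectional*
LSTM on the fused (post-encoding) sequence, concatenated with the BiLSTM
output before pooling — an interpretation, flagged as such. The enlarged
ReLU/Tanh variants are emulated by a `width_multiplier` that scales the
fusion dimension, feed-forward width and LSTM hidden size; the default
multipliers (2.05 and 1.78) were calibrated once against the reference
parameter counts (9.34 M / 7.07 M, matched within ±2 %) and are
estimates, not reported architecture facts. Initialization is fan-based
uniform, seeded; dropout inside the transformer residual paths is 0.1
(within the 0.3–0.5 range used elsewhere in the model; the
transformer sites are unnamed, so the conventional small rate is used).

The entire network — convolutions, batch-norm, attention, LSTM,
backpropagation, Adam — is implemented in base R with explicit
forward/backward passes per layer. The test suite verifies the
backpropagation against central finite differences, sampling one entry
of every parameter tensor in every layer type (tolerance 1e-4 relative).

## Training and transfer

Three regimes: scratch (150 epochs, Adam lr 1e-3), full fine-tuning
(150 epochs, 5e-4) and reduced fine-tuning (75 epochs, 5e-5); batch 64,
cross-entropy. Transfer = pretrain on pooled source subjects, then
fine-tune on the target under a freeze policy: convolutional and
recurrent layers fully trainable, transformer encoder partially frozen.
"Partially" is unquantified; the default freezes the lower half (layers
0–3 of 8, configurable 0–8) on the rationale that lower layers hold the
most general representations. Model selection takes the best validation
accuracy, earliest epoch on ties (a validation set is implied but no
selection rule is stated). No scheduling, weight decay or augmentation:
none is named. Cross-geometry transfer (3-channel source → 22-channel
target) is geometrically impossible without adaptation; the adapter
rebuilds and re-initializes the spatial stage (first convolution of each
branch) while copying every shape-compatible tensor — again an
interpretation, recorded in the checkpoint provenance.

Everything is deterministic under seeds: identical plans reproduce
bit-identical training histories.

## Evaluation

One LOSO fold per subject; the held-out subject appears in no training
or validation batch (asserted at run time, per fold). Within a fold the
validation set is carved, stratified, from the training subjects only
(20 % by default; the protocol fixes no fraction). Metrics come from
per-subject confusion matrices: accuracy (percent), macro-averaged F1
(macro is the declared standard; a class with no predictions and no
instances contributes 0), Cohen's κ with chance agreement from the
marginals. Aggregates are the across-subject mean and standard
deviation. Two summary statistics connect accuracy to cost and
stability:

* efficiency index **η = A / P** (accuracy fraction per million
  trainable parameters, 3 decimals),
* variance-reduction ratio **Δσ = (σ_baseline − σ_TL)/σ_baseline ×
  100 %** (1 decimal).

Paired two-tailed t-tests compare subject-level accuracies; p-values are
reported uncorrected (whether multiple-comparison correction was applied
is left open by the protocol) with degenerate zero-variance cases handled
explicitly (identical vectors: t = 0, p = 1).

## Baselines

* **CSP + LDA**: per-trial covariances are trace-normalized before
  class-averaging (a standard stabilization);
  filters jointly diagonalize the class covariances in the whitened
  convention (eigenvalue pairs sum to 1); 4 components by default, log
  relative variance features, LDA with a jitter fallback on degenerate
  covariance. Strictly two-class: the multiclass extension is declared
  out of scope rather than guessed.
* **Random forest**: each trial flattened to channels × samples
  features, one classifier per subject, 200 trees, depth 20, seeded.
* **Band-power + LDA probe**: log variance in the mu and beta bands per
  channel — used chiefly to certify that synthetic data is decodable
  (LOSO accuracy > 75 % at `erd_depth = 0.6`, chance at 0).

## Numerical choices and degenerate inputs

Ties in model selection go to the earliest epoch; split rounding is
half-to-even with largest-remainder repair (ties to the lower class
index); constant channels hit the standardizer floor with a warning;
rank-deficient CSP covariances get a logged ridge; softmax
cross-entropy subtracts the per-column maximum before exponentiation;
batch-norm uses ε = 1e-5 and momentum 0.1.

## Problem sizes used in the shipped tests

The test and acceptance suites run the full pipeline at reduced widths
chosen as the smallest sizes at which every contract is still
meaningfully exercised: cohorts of 1–3 synthetic subjects with 6–20
trials per class, ~1 s epochs (256 samples), and a network with
8/12-filter branches, fusion dimension 16, one transformer layer and one
8-unit BiLSTM layer. The deep-learning sanity checks are a 16-trial
overfit (training accuracy must reach 1.0 within 150 epochs) and a
scaled-down scratch-vs-transfer comparison whose accuracy difference is
reported descriptively — at these sizes the direction of the difference
is noisy, and gating on it would test the random seed, not the code.
Full-width constructions (22 channels × 1125 samples, 8 transformer
layers) are exercised for shape, determinism and parameter-count
contracts.

## Known limitations

The generator's independence across channels and trials is a deliberate
simplification; CSP on such data has an easier job than on real EEG. The
R implementation of the network favors auditability over speed: it is
entirely adequate for the desk-scale contracts shipped here, but
full-scale benchmark training is not its purpose and reproducing
benchmark accuracy tables is out of its scope. Width multipliers for the enlarged
variants reproduce parameter counts, not the (undescribed) architectures
behind them.
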