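# midecode

Subject-independent decoding of motor-imagery EEG with a hybrid
convolutional–attention–recurrent network family, transfer learning, and
leave-one-subject-out (LOSO) evaluation — implemented end-to-end in R,
exercisable entirely on synthetic data.

## The problem

Imagined limb movement suppresses the sensorimotor mu (8–12 Hz) and beta
(13–30 Hz) rhythms over the contralateral motor cortex — event-related
desynchronization (ERD). A motor-imagery brain–computer interface decodes
these band-power changes from multichannel EEG. The hard part is
*subject-independence*: EEG statistics differ so much across people that a
decoder trained on one cohort often collapses on a new user.

`midecode` implements a complete experimental framework for this problem:

* **Synthetic ERD generator** (`synth_spec()`, `generate_dataset()`) —
  cue-locked trials of 1/f background plus band-limited mu/beta rhythms,
  class-lateralized ERD after the cue, per-subject log-normal gains, and
  optional large electrooculogram (EOG) artifacts. Every downstream stage
  is testable without any data download.
* **Preprocessing** (`preprocess_pipeline()`) — common-average reference,
  cue-locked epoching, EOG trial rejection (strict ±100 µV), zero-phase
  fourth-order Butterworth band-pass (8–30 Hz), per-subject stratified
  train/validation/test splits, and per-channel standardization fitted on
  training data only.
* **Model family** (`model_config()`, `make_preset()`, `build_model()`) —
  two parallel convolutional branches (64 deep + 80 shallow filters) fused
  to a 128-dimensional sequence, sinusoidal positional encoding, an
  8-layer transformer encoder (4 heads, GELU), a 3-layer bidirectional
  LSTM (128 units/direction), temporal mean pooling and an MLP head; plus
  a simplified from-scratch variant (6 transformer / 2 BiLSTM layers, no
  positional encoding) and enlarged ReLU/Tanh activation variants. The
  network, backpropagation and Adam are implemented in base R.
* **Training & transfer** (`train_model()`, `pretrain_then_finetune()`) —
  from-scratch (150 epochs, lr 1e-3), aggressive fine-tuning (150 epochs,
  5e-4) and conservative fine-tuning (75 epochs, 5e-5), with selective
  freezing: convolutional and recurrent layers stay trainable while the
  lower transformer layers are frozen to prevent catastrophic forgetting.
* **Evaluation** (`loso_evaluate()` and metrics) — accuracy, macro-F1,
  Cohen's κ from per-subject confusion matrices, paired two-tailed
  t-tests, the efficiency index **η = A / P** (mean accuracy as a fraction
  per million trainable parameters), and the variance-reduction ratio
  **Δσ = (σ_baseline − σ_TL) / σ_baseline × 100 %**.
* **Baselines** (`csp_lda_factory()`, `random_forest_baseline()`,
  `bandpower_lda_probe()`) — common spatial patterns + LDA, flattened-trial
  random forests (200 trees, depth 20), and a log-band-power LDA probe.
* **Workbench** (`experiment_spec()`, `run_experiment()`) — the five
  standard comparisons (scratch vs transfer, full vs reduced fine-tuning,
  activation ablation, cross-geometry validation, shallow baseline) with
  JSON/CSV reports, provenance manifests and a self-consistency audit.

A thin command-line front end ships in `inst/cli/midecode`
(`synth`, `preprocess`, `train`, `finetune`, `loso`, `baseline`,
`experiment`, `report`).

## Worked example

Generate a small synthetic cohort, check it is decodable with the shallow
probe, then run the scaled-down transfer-learning comparison:

```r
library(midecode)

ds <- generate_dataset(synth_spec(
  n_subjects = 3, n_trials_per_class = 20, n_classes = 2,
  erd_depth = 0.6, snr = 2, seed = 81))
ds
#> <eeg_trialset> 120 trials x 3 channels x 1125 samples @ 250 Hz
#>   classes: 2  subjects: 3  window: [-0.5, 4] s  eog: 3

rep <- loso_evaluate(bandpower_lda_factory(), ds, seed = 5)
rep
#> <loso_report> 3 subject folds: accuracy 100.00% +/- 0.00, macro-F1 1.000, kappa 1.000
```

A LOSO accuracy far above the 50 % chance level confirms that the
generator produces the class-conditional band-power contrast the deep
models are built to exploit (with `erd_depth = 0`, the same probe stays at
chance). The statistics reported throughout follow the same conventions:

```r
efficiency_index(A = 0.7944, P = 1.38)   # 0.576 accuracy-fraction per M params
variance_reduction(20.49, 11.09)         # 45.9 % less across-subject spread
```

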