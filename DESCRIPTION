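Package: midecode
Title: Subject-Independent Motor-Imagery EEG Decoding with Hybrid
    Convolutional-Attention-Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for subject-independent decoding of motor-imagery
    electroencephalography (EEG). Provides a synthetic generator of
    event-related desynchronization (ERD) trials over a 1/f background,
    a reproducible preprocessing pipeline (common-average reference,
    cue-locked epoching, electrooculogram-based trial rejection,
    zero-phase Butterworth band-pass filtering, train-only
    standardization, stratified splitting), a hybrid deep network family
    combining parallel convolutional branches, a transformer encoder and
    a bidirectional LSTM with transfer-learning fine-tuning under
    selective layer freezing, leave-one-subject-out (LOSO) evaluation
    with accuracy, macro-F1 and Cohen's kappa, efficiency and
    variance-reduction statistics, and shallow baselines (common spatial
    patterns with linear discriminant analysis, random forests, and a
    band-power probe).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    randomForest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
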