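Package: midecode
Title: Motor-Imagery EEG Decoding with a Hierarchical CNN-BiLSTM-Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes motor-imagery EEG trials with a three-stage deep network:
    a convolutional spatial-spectral encoder, a bidirectional LSTM temporal
    encoder, and a patch-tokenized Transformer head, trained with AdamW and
    evaluated under within-subject, leave-one-subject-out, and subject-specific
    fine-tuning protocols. A model-agnostic meta-learning (MAML) engine learns
    initializations that adapt to new subjects from a few labeled trials, and a
    multi-objective evolutionary search (NSGA-II) explores the architecture
    space against accuracy, compute, and parameter-count objectives. Includes a
    signal-conditioning chain (zero-phase Butterworth band-pass, notch,
    resampling, epoching, artifact rejection, per-trial normalization) and a
    synthetic event-related-desynchronization generator so the whole pipeline
    is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
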