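Package: protobeat
Title: Interpretable Prototype Learning for Heartbeat Time-Series Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prototype-based classification of fixed-length physiological
    time-series segments (single ECG heartbeats). A stacked bidirectional
    LSTM encoder with additive attention pooling maps each beat to a latent
    embedding; a layer of trainable prototype vectors converts embeddings to
    exponential similarities, and a linear head classifies from those
    similarities. Training minimizes cross-entropy plus diversity,
    prototypicality and clustering regularizers. Prototypes are projected
    onto their nearest training exemplars so every prototype can be shown as
    a real waveform, and an editing layer supports expert-driven prototype
    generation, validation, removal, pruning and fine-tuning. Includes a
    seeded synthetic generator of normal-sinus, atrial-fibrillation and
    other-rhythm beat morphologies, CSV and WFDB readers, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
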