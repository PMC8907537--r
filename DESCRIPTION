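Package: eegdgcn
Title: Dynamic Graph Convolutional Networks with Style Recalibration for
    EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies emotional state from multichannel EEG using
    differential-entropy band features fed through a multi-layer graph
    convolutional network whose channel-connectivity adjacency matrix is
    itself a trainable parameter, followed by a style-recalibrated
    convolutional stack and a multi-level fusion classifier.  Provides
    functional-connectivity initializers (absolute Pearson correlation,
    phase-locking value, random), a from-scratch training loop with Adam
    and L2 regularization, trial-based train/test splits, post-hoc
    analysis of the learned connectivity (top-k edge ranking on named
    10-20 channels), and a synthetic-data generator with class-conditional
    connectivity graphs so the whole pipeline can be exercised and tested
    without access-restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
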