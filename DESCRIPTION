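Package: tapcrnn
Title: Temporal Attentive Pooling Convolutional Recurrent Networks for
    Heart Murmur Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects holosystolic murmurs in phonocardiogram (PCG)
    recordings with a convolutional recurrent neural network equipped with
    temporal attentive pooling (TAP). The TAP mechanism combines a global
    attention over all spectrogram frames, conditioned on convolutional
    features and the final recurrent state, with a local refinement
    attention; the per-frame product of the two attention weights is an
    event presence likelihood (EPL) that localizes murmur evidence in
    time. The package provides STFT log-power featurization, CNN and CRNN
    baselines, subject-exclusive train/test and k-fold evaluation
    protocols with sensitivity/specificity/PPV/NPV/ROC reporting, a
    seeded synthetic phonocardiogram simulator with ground-truth systolic
    annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
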