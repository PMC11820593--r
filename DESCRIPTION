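Package: ecgfusion
Title: Dual-Channel ECG Arrhythmia Classification with ICEEMDAN Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for five-class (AAMI) arrhythmia
    classification from single-lead ECG. Signals are denoised by improved
    complete ensemble empirical mode decomposition with adaptive noise
    (ICEEMDAN) combined with an improved wavelet threshold function and a
    1.5 Hz baseline-wander rule, cut into overlapping 5-second slices with
    rule-based slice labeling, class-balanced by SMOTE, and encoded as
    Gramian angular difference field, Markov transition field and recurrence
    plot images. Classification uses a dual-channel network: a 1-D residual
    network with an improved convolutional block attention module (ICBAM) on
    the raw slice, and a 2-D convolutional branch on the stacked image
    encoding, fused by concatenation and a softmax head. Includes a WFDB
    format-212 reader/writer, an annotated synthetic ECG generator so every
    stage is testable without external data, and a full evaluation-metric
    suite (confusion matrix, per-class PPV/Sen/Spec/F1/Acc, overall
    accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
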