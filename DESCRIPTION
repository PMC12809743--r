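Package: neuroplaylist
Title: Closed-Loop In-Ear EEG Decoding of Musical Pleasure and Playlist Generation
Version: 0.1.0
Authors@R:
    person("Open", "Research", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for closed-loop neurofeedback playlist
    generation from two-channel in-ear electroencephalography (EEG). Includes
    spectral-feature preprocessing of ear-canal EEG (Butterworth filtering,
    artifact-component removal, sliding-window epoching, Welch power spectral
    density binning, noise flagging), a sparse linear model predicting
    subjective pleasure ratings from frame-level audio embeddings, a
    PCA + logistic LASSO classifier of high- versus low-pleasure EEG states
    with permutation-test validation and weight back-projection, composite
    ranking of a candidate-song library, real-time pleasure decoding with
    moving-average smoothing, and the closed loop in which decoded pleasure
    retrains the acoustic model and re-ranks songs. A synthetic-data module
    generates EEG, audio embeddings, chill key-press events and visual analog
    scale ratings with the statistical structure the pipeline assumes, so the
    whole system is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
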