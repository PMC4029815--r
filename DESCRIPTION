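Package: rtnf
Title: Closed-Loop Simulation and Analysis of Real-Time fMRI
    Neurofeedback Decoding Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing two-class real-time fMRI
    neurofeedback experiments in which a linear support vector machine
    decodes emotional brain states (tenderness versus pride) volume by
    volume and drives a 20-level visual feedback signal.  Provides a
    block-design protocol generator, a closed-loop synthetic-subject
    simulator with a feedback-dependent learning effect, incremental
    (volume-wise) preprocessing with neutral-baseline normalisation,
    decoder training and per-session retraining, decision-value-to-ring
    feedback mapping, group-level classification statistics (t tests and
    exact binomial tests), discriminant-weight consistency maps, and an
    offline block GLM with HRF convolution, DCT high-pass drift terms and
    permutation-based small-volume family-wise error correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
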