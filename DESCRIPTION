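Package: mindfc
Title: Resting-State Thought Content, Connectivity Fingerprints, and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links self-reported thought content during resting-state fMRI to
    functional-connectivity (FC) fingerprints and behavioral phenotypes.
    Provides node-level denoising (confound regression, cosine drift basis,
    zero-phase low-pass filtering, motion-based run exclusion), Fisher-z FC
    matrices with half-vectorized fingerprints and network-aggregated (FNC)
    summaries, within-subject run-pair similarity tables analyzed with
    random-intercept mixed models, canonical correlation analysis against a
    univariate behavioral outcome, and bootstrap mediation of FC-behavior
    associations through thought-content canonical variates. A seeded
    synthetic-data generator with a planted mediation structure supports
    power analysis and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
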