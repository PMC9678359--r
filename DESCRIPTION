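Package: insulacoder
Title: Intensity Coding Statistics for Intracranial EEG Broadband Power
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for quantifying how intracranial EEG broadband
    activity encodes the perceived intensity of observed pain. Provides
    Hanning-taper time-frequency decomposition with baseline percent-change
    normalization, trial-wise Spearman intensity-coding statistics,
    circular-shift and condition-shuffle cluster permutation tests,
    patient-stratified whole-brain resampling nulls, one-sided binomial and
    Bayes-factor inference (binomial enrichment, JZS t-test, correlation),
    quadrant classification of stimulus preference, partial least squares
    decoding with shuffle nulls and cross-stimulus generalization, video
    motion-energy and facial action-unit temporal analyses, spike-train
    screening, and rating-behavior analytics. A synthetic-data generator
    reproduces the statistical structure of a seven-patient cohort so the
    whole pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    EBImage,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
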