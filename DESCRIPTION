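Package: facekin
Title: Facial Kinematics of Character and Emotion Portrayal from 3D Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing facial expansion and contraction from 3D
    motion-capture marker trajectories during spoken performance. Computes
    per-frame Euclidean lengths of facial segments (brow, eyebrows, lips,
    jaw) from labelled marker pairs, averages them per trial while omitting
    reconstruction gaps, and normalises trial means to each subject's
    neutral-speech baseline as percent change, removing face-size and
    speech-articulation effects. Provides mixed-effects repeated-measures
    ANOVAs (type III, Satterthwaite degrees of freedom) over a 3x3
    cooperativeness-by-assertiveness character scheme and a 2x2
    valence-by-arousal emotion grouping, Pearson face-voice correlations
    with Fisher confidence intervals, a varimax-rotated principal-component
    analysis of combined facial and vocal parameters, and a fully synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
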