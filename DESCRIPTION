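Package: ecslice
Title: Single-Cell Electrophysiology, Voltage-Sensitive Dye Imaging and
    Nested Cohort Statistics for Entorhinal-Hippocampal Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction for whole-cell current-clamp recordings of
    entorhinal Layer II neurons (input resistance with anomalous
    rectification, membrane time constant, sag ratio and rebound, rheobase,
    action-potential waveform metrics with threshold from the second
    derivative, spike-train and f-I statistics, ZAP subthreshold resonance,
    quality-control exclusions, and Henderson liquid junction potentials),
    quantification of voltage-sensitive dye imaging movies (trial averaging,
    dF/F, spatial and cubic temporal filtering, ROI integrals, activated-area
    thresholding, paired-pulse ratios, stripe profiles), nested linear mixed
    models with covariance-structure selection and balanced estimated
    marginal means for cells-within-animals designs, delta-delta-Ct
    genotyping arithmetic, and synthetic-data generators (resonate
    exponential-integrate-and-fire cells, dentate gyrus two-blade imaging
    scenes, multi-animal cohorts) with closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nlme,
    minpack.lm,
    signal,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
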