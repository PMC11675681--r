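Package: hrasleep
Title: Heart Rate Asymmetry and Variability Descriptors for Sleep Stage Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed analysis of RR-interval time series recorded during sleep:
    time-domain and spectral heart rate variability, Poincare-plot asymmetry
    decompositions (SD1d/SD1a, SD2d/SD2a, SDNNd/SDNNa), deceleration and
    acceleration runs with their Shannon-entropy partition (HDR/HAR),
    threshold-based asymmetric counts (pNN30dec/pNN30acc), and sample entropy.
    Segments are labeled with certain sleep stages and stage transitions from an
    expert hypnogram by fractional-occupancy rules, and stage membership is
    modeled one-versus-all with generalized estimating equations (logistic link,
    subject clusters, exchangeable/AR1/independence working correlation, robust
    sandwich errors, backward AIC selection). Includes a synthetic
    polysomnography-like cohort generator with stage-conditioned RR dynamics for
    end-to-end validation, plus confusion-matrix and AUC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
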