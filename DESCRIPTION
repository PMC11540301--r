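Package: axonav
Title: Analysis of Single-Axon Calcium Activity During Virtual-Reality Navigation
Version: 0.1.0
Authors@R:
    person("axonav", "developers", email = "axonav@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium-imaging recordings of
    single neuromodulatory axons (dopaminergic and noradrenergic projections
    to hippocampal CA1) during head-fixed virtual-reality navigation.
    Provides a documented on-disk session format, a synthetic-session
    generator with known ground-truth encodings, behavioural derivation
    (Savitzky-Golay velocity, lap segmentation, immobility and motion-onset
    detection), trace quality control (rolling-percentile dF/F, correlated
    ROI merging, power-spectral-density SNR filtering against
    autofluorescent controls, CUSUM sustained-shift exclusion),
    covariate-binned tuning curves and event-aligned activity matrices,
    regression-based encoding classification with resampling comparisons,
    ANCOVA/ANOVA with Tukey HSD, and a shuffle-bootstrap null band for
    novelty-response detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
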