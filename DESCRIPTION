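Package: eegburst
Title: Multi-Feature Burst Detection for Preterm Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bursts and inter-burst intervals in the discontinuous
    (trace discontinu) EEG of very preterm infants. Per-channel amplitude,
    spectral-shape and frequency-weighted-energy features are extracted on a
    common 64 Hz grid, reduced by maximum-relevance minimum-redundancy (mRMR)
    feature selection with a backwards-elimination wrapper, and fused by a
    linear support vector machine into a per-sample burst / inter-burst
    segmentation. Includes consensus-annotation handling, nested leave-one-out
    cross-validation, sample- and event-based detection metrics, Cohen's kappa
    with bias and prevalence indices, inter-burst-interval summary statistics,
    and a synthetic generator of discontinuous EEG for end-to-end testing
    without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
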