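Package: audiodx
Title: Synthetic Audiogram Digitization and Tinnitus Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bed for diagnosing tinnitus
    from extended high-frequency audiometry (0.25-16 kHz). Simulates labeled
    per-ear threshold profiles, renders them as audiogram chart images with
    ground-truth sidecars, detects audiometric symbols with per-ear boosted
    Haar-feature cascades, calibrates pixel coordinates back to (frequency,
    dB HL), imputes missing thresholds by chained equations with predictive
    mean matching, extracts the three high-frequency features (band mean,
    band standard deviation, any-threshold-above-30-dB), and classifies ears
    with from-scratch L2-regularized logistic regression, a small
    feed-forward network, and a majority-class baseline, evaluated with a
    from-scratch diagnostic-metrics suite (confusion matrix, classification
    report, rank-based ROC-AUC, Cohen's kappa, MCC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
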