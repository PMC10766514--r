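Package: dagoat
Title: Dynamic Risk Scoring for Severe Acute GVHD from Irregular Clinical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements daGOAT, a dynamic probabilistic model that integrates
    multidimensional, irregularly sampled post-transplant time series into a
    daily-updated risk score for severe acute graft-versus-host disease onset
    within a moving two-week window. Provides the data-cleaning pipeline
    (outlier blanking, daily averaging, time-limited sample-and-hold), the
    model fit (mutual-information discretization cutoffs, per-day conditional
    bin probabilities, smoothing-spline estimates, a Naive Bayes prior over
    peri-transplantation features), time-varying evaluation (daily AUROC and
    AUPRC with bootstrap confidence intervals, sextile hazard ratios,
    leave-one-feature-out importance timelines), benchmark models (Random
    Forest, XGBoost), landmark plasma-biomarker comparator scores, a
    simulation engine for benchmarking under controlled complexity,
    smoothness and missingness, and an adapter for the smartphone
    activities/postural-transitions dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    optparse
Config/testthat/edition: 3
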