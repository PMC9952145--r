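Package: ppgscreen
Title: Two-Stage Cardiovascular Disease Screening from Photoplethysmogram Time-Domain Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates photoplethysmogram (PPG) cohorts with analytic
    ground-truth fiducials, preprocesses recordings with a zero-phase
    elliptic band-pass filter, segments beats, locates pulse-wave landmarks
    (systolic peak, dicrotic notch, acceleration-plethysmogram a/b/e waves),
    computes 24 per-beat time-domain features with per-subject aggregation,
    screens features with Welch t-tests, performs greedy stepwise wrapper
    feature selection, and evaluates a two-stage cascade classifier
    (healthy vs cardiovascular disease, then five-way disease typing) with
    class rebalancing and stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
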