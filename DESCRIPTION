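Package: zonescreen
Title: Event-Zone Time-Series Clustering for Virtual Driving-Test Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screening-test analysis of simulated driving assessments. Drives
    recorded as multichannel telemetry (lane offset, throttle, brake, steering)
    are partitioned into predefined event zones, per-zone behavior is clustered
    with dynamic time warping and k-medoids, and soft-clustering medoid
    dissimilarity features are fed to pass/fail classifiers evaluated with a
    screening metric suite (risk ratio with 95% confidence interval, false-alarm
    ratio, ROC/AUC). Includes a synthetic drive simulator with planted
    prototypical behaviors and skill-linked on-road-exam scores, a 67-variable
    engineered feature set for comparison, and exact reconstruction of integer
    confusion matrices from rounded printed screening metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    glmnet,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
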