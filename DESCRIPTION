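Package: uavabund
Title: Wildlife Abundance Estimation from Automated Drone Survey Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Abundance estimation for wildlife detected automatically in
    thermal imagery from drone (RPAS) surveys, where automated detectors
    introduce false detections and duplicate detections alongside ordinary
    imperfect detection. Implements a modified Horvitz-Thompson estimator
    whose per-object weights are driven by fitted logistic models of
    detection, false-detection and duplicate-detection probability, and a
    generalized N-mixture model on distance-binned transect counts with
    uniform or half-normal detection key functions, visit-level availability
    and negative-binomial latent abundance. Includes a synthetic-survey
    generator with known truth for parameter-recovery and interval-coverage
    experiments, AIC-based stepwise model selection, and a Freeman-Tukey
    parametric-bootstrap goodness-of-fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
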