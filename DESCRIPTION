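Package: stancesim
Title: Muscle-Actuated Simulation of Human Quiet Standing with Delayed
    Feedback Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of planar (sagittal-plane) musculoskeletal
    standing balance under neurological time delay. Provides generalized-
    coordinate rigid-body dynamics for floating-base kinematic trees,
    Hill-type muscular-tendon actuators with first-order activation dynamics
    and asymmetric activation/deactivation time constants, Hunt-Crossley
    compliant foot-ground contact with velocity-dependent friction, and a
    neural controller combining constant feed-forward muscle activations with
    delayed, length-normalized proportional-derivative feedback on
    muscular-tendon length and velocity. A two-stage design pipeline derives
    the controller variables: a grid search over shared PD gains harvests
    feed-forward activation candidates from zero-delay stance trials, and a
    covariance-matrix-adaptation evolution strategy (CMA-ES) then optimizes
    the nine-group gain set under the full 120-ms loop delay. Evaluation
    utilities compute center-of-mass/center-of-pressure sway ranges, joint
    angle correlations, activation-range deviations and phase portraits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
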