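Package: rewardadapt
Title: Reward-Gated Learning Dynamics in Visuomotor Rotation Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analytics for sensorimotor adaptation driven solely by
    rewards. A two-layer linear network with a ring of direction-tuned input
    neurons learns to counter an imposed visuomotor rotation through a
    reward-modulated (REINFORCE-style) plasticity rule gated by binary, smooth,
    or stochastic rewards. The package provides the trial-loop engine (with
    target-size and rotation-angle shaping schedules), closed-form results for
    the reward probability (Rice distribution), the small-target-limit learning
    dynamics and worst-case error bounds, generalization and interference
    functions, and ensemble statistics for learning durations, cross-target
    error correlations, delayed learning, and ordered multi-target learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
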