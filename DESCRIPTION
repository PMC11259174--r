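Package: fireflynav
Title: Partially Observable 'Firefly' Navigation: Simulator, Kalman-Filter
    Beliefs, Modular Actor-Critic Agents, and Analysis
Version: 0.1.0
Authors@R:
    person("Firefly", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A desk-scale research platform for the 'firefly' virtual
    navigation task: a continuous-state, continuous-action POMDP in which an
    agent steers toward a transiently visible target using noisy self-motion
    cues. Provides the task simulator with joystick-gain and perturbation
    variants, extended-Kalman-filter belief estimation in target-relative
    coordinates with a particle-filter verification oracle, actor-critic
    reinforcement-learning agents (twin-delayed deterministic policy
    gradient) with a family of architectures of graded module
    specialization, and the behavioral and neural analysis battery:
    psychometric/ROC stopping accuracy, signed radial error along idealized
    circular arcs, trajectory curvature and length, ridge decoding of
    position from hidden units, spatial tuning maps, and Kalman-gain
    fingerprinting under uncertainty mismatch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
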