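Package: roboshoal
Title: Virtual Ethorobotics Laboratory for Zebrafish Door-Choice Learning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested software laboratory for robot-demonstrator zebrafish
    observational-learning experiments. Simulates stochastic burst-and-coast
    swimming in a two-door choice tank, scripts the robotic replica's
    demonstration protocol, reconstructs positions from frame sequences by
    frame differencing with Kalman gap filling, applies the closed-loop
    door-trigger rule (3 s of presence in any trailing 5 s window), computes
    the full set of behavioral and learning measures (door preference index,
    reward index, trajectory entropy, heading error, kinematics, freezing,
    avoidance), and analyzes repeated trials with linear mixed models,
    type II Wald chi-square tables, interaction pruning, and Levene's
    (Brown-Forsythe) variability test. A counterbalanced synthetic cohort
    generator with injectable learning drift and side bias provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    png,
    digest,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
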