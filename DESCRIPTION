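Package: sattrain
Title: Stress-Adaptive Training from Grip Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stress-adaptive psychomotor training driven by grip
    force. Estimates operator stress in real time as a capped moving z-score
    of grip force, adapts task difficulty continuously from the stress signal
    with a hysteresis controller, and evaluates training quality
    (time-to-criterion and performance-at-criterion from a first-derivative
    learning-curve cutoff) against constant-difficulty and time-ramp control
    policies. Includes a closed-loop synthetic trainee (mean-reverting latent
    stress, inverted-U stress-performance link, saturating learning curve,
    Poisson event streams) so the full pipeline can be exercised and power
    analysed without human data, plus speed yoking and condition-contrast
    statistics for three-arm training experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
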