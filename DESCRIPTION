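Package: modeseek
Title: Mode-Resolved Classification-Image Analysis of False Alarms in
    Gabor-in-Noise Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how dynamic predictive templates drive false
    alarms in visual detection. Simulates Gabor-in-noise detection experiments
    with a two-state (external/internal mode) Markov observer, computes
    orientation-power profiles of noise stimuli by 2-D Fourier analysis,
    derives classification images and their polar average vectors, fits
    one-state logistic GLMs and two-state Bernoulli GLM-HMMs by MAP-EM with
    BIC model comparison and permutation controls, and reproduces the
    associated regression and shift statistics (alarm-rate predictors,
    mode-conditional serial dependence, false-alarm rates by mode,
    classification-vector displacement tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
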