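Package: talkerlearn
Title: Simulation and Analysis of Talker Identification Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools to simulate and analyze talker-identification learning
    experiments that pair choice and response-time data with trial-locked
    pupillometry. Includes a generative study simulator built on a
    multi-alternative Wiener race (inverse-Gaussian first-passage times),
    mixed-effects analyses of accuracy and response time, Bayesian fitting
    of the race model with block-varying drift and threshold parameters,
    pupil preprocessing (windowing, downsampling, blink screening and
    interpolation, baseline normalization), growth curve analysis with
    orthogonal polynomial time terms, and error-pattern analysis relating
    behavioral confusion matrices to acoustic similarity between talkers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    lmerTest,
    car,
    yaml,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
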