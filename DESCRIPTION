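Package: ampop
Title: Population-Code Analysis of Apparent-Motion Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for modelling two-alternative forced-choice (2AFC)
    contrast detection in the presence of apparent motion (AM). Implements a
    V1-like contrast-normalization population code with von Mises
    orientation tuning and Naka-Rushton contrast responses, an AM-extended
    response equation with excitation, divisive inhibition and
    response-gain suppression terms, a linear summation decoder mapping
    population activity to proportion correct, maximum-likelihood fitting
    of logistic psychometric functions with a free performance ceiling and
    of the full population model under physiological constraints,
    parametric-bootstrap inference (confidence intervals, deviance
    goodness-of-fit, ceiling comparisons, AIC-based nested model
    comparison), and a synthetic 2AFC observer for validation, calibration
    and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
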