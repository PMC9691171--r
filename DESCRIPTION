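Package: selmnp
Title: Panel Multinomial Probit with Sample Selection for Healthcare-Needs Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint estimation of a two-equation system in which a binary
    selection outcome (experiencing healthcare needs) governs observation of a
    four-category outcome (met needs, or unmet needs due to financial
    difficulty, time constraint, or lack of caring and support).  Latent
    utilities carry correlated multivariate-normal errors; rectangle
    probabilities are simulated with the Geweke-Hajivassiliou-Keane (GHK)
    recursion on antithetic Halton draws and the weighted pseudo-likelihood is
    maximised by quasi-Newton iterations with common random numbers.  Includes
    survey-outcome coding, design-matrix construction with collinearity
    diagnostics, cluster-robust sandwich variance for longitudinal survey
    weights, Hosmer-Lemeshow and information-criterion diagnostics, average
    adjusted probabilities over an age-by-gender grid with delta-method
    confidence intervals, and a synthetic panel generator emulating the
    structure of a national health panel survey.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    nnet,
    pracma,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
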