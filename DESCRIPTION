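Package: frimpact
Title: Predator Functional Responses and Relative Impact Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Type II predator functional responses to depletion-style
    consumption trials with the Rogers random predator equation (solved via
    the Lambert W function), classifies functional response types by
    quasibinomial logistic regression, compares attack coefficients and
    handling times between predator groups with indicator-variable joint
    fits, and propagates uncertainty by nonparametric bootstrap. Per capita
    effects (maximum feeding rates) are combined with quadrat-based field
    abundance estimates into the Relative Impact Potential metric via Monte
    Carlo sampling, with exceedance probabilities, confidence intervals and
    biplot summaries. Includes a stochastic simulator of depletion trials
    and overdispersed quadrat surveys, contingency-table tests of predation
    frequency, quasi-Poisson abundance comparisons, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
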