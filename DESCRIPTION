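Package: thymodel
Title: Optimal-Control Models of Thymic Involution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the age-dependent optimal production schedule of naive
    T cell clones from the thymus under a trade-off between the cost of
    fighting novel pathogens (inversely proportional to peripheral repertoire
    diversity) and the cost of maintaining thymic output. Provides the
    closed-form quasi-static optimum under rapid peripheral turnover
    (exponential or power-law involution depending on the variability of
    pathogen encounter rates), the full dynamic optimum via Pontryagin's
    Maximum Principle (bang-bang and singular-arc schedules with switching
    times), an independent adjoint-gradient direct optimizer, and a Monte
    Carlo simulator of pathogen-encounter life histories for validating the
    expected-cost structure of the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
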