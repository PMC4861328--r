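Package: cvdburden
Title: Financial Burden and Impoverishment from Out-of-Pocket
    Cardiovascular Medicine Purchase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the impoverishing effect of out-of-pocket purchase
    of cardiovascular medicines from aggregated household expenditure
    data. Builds cost-effectiveness ranked step-up prevention regimens
    from a ceiling-price drug catalog, reconstructs monotone expenditure
    quantile curves from grouped monthly per-capita expenditure brackets
    by monotonicity-preserving cubic Hermite interpolation, computes
    poverty headcount ratios and poverty gap indices before and after
    medicine purchase, allocates the adult population to regimens through
    a cardiovascular risk cascade, and combines the pieces into
    population burden estimates with univariate (tornado) sensitivity
    analysis. Includes a synthetic microdata generator to validate the
    aggregate-data method against micro-data ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
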