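Package: dfpsindirect
Title: Indirect Estimation of Demand for Family Planning Satisfied from
    Contraceptive Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating demand for family planning satisfied
    (DFPS, by any and by modern contraceptive methods) in settings where the
    fertility-intention and fecundity questions needed for direct estimation
    are unavailable. Implements the woman-level classification rules for
    contraceptive use, method type (Hubacher-Trussell modern-method list),
    infecundity and need for contraception; survey-weighted indicator
    estimation over population strata; published fractional-polynomial
    logit-regression predictors mapping contraceptive prevalence (CPR) to
    DFPS; fractional-polynomial model search with country-clustered
    standard errors; k-fold cross-validation on the back-transformed scale;
    and a synthetic survey-data generator so every stage is testable
    without access to household-survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
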