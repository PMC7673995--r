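Package: idascreen
Title: Predicting Drug Combination Efficacy from Monotherapy Cell Line
    Screens under Independent Drug Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the efficacy of cancer drug combinations
    from high-throughput monotherapy cell line viability screens under the
    independent drug action (IDA) null model, with Bliss Independence as a
    comparator. Includes readers and harmonization utilities for long-format
    screen exports, four-parameter log-logistic dose-response fitting with
    heteroskedasticity-consistent parameter covariance, translation of
    predicted mean viabilities into clinical-trial hazard ratios and
    Freedman-type log-rank powers, prospective ranking of combinations with
    the IDAcomboscore, a semi-parametric bootstrap with shared-compound
    coupling for uncertainty estimation, and a synthetic screen generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
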