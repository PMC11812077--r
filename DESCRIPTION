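Package: bcsrr
Title: Random-Regression Test-Day Prediction of Body Condition Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-trait random-regression test-day modelling for dairy
    cattle, aimed at predicting body condition score (BCS, 9-point scale)
    across an entire first lactation from a single BCS record per cow plus
    routine milk-recording data (milk yield, fat and protein percentage).
    Implements pedigree relationship matrices and their sparse inverses with
    inbreeding, second-order Legendre covariance functions, assembly and
    solution of Henderson's mixed-model equations with per-record
    missing-trait residual handling, EM-REML variance-component estimation
    with sparse inverse-subset trace computation, cross-trait residual
    imputation for BCS prediction, ordinal agreement statistics (Cohen's
    kappa, three weightings), and a pedigree-structured synthetic test-day
    data generator with known simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
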