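Package: mrpath
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: instrument selection (p-value thresholding, greedy
    LD clumping, outcome-association exclusion, exclusion lists, minor
    allele frequency and F-statistic filters), allele harmonization with
    palindromic-variant handling, the five standard causal estimators
    (inverse-variance weighted, MR-Egger, weighted median, weighted mode
    and simple mode), sensitivity diagnostics (Cochran's Q, the MR-Egger
    intercept test, MR-PRESSO global/outlier/distortion tests and
    leave-one-out analysis), candidate screening with corroboration and
    direction rules, reverse MR, and product-of-coefficients mediation
    decomposition for exposure-mediator-outcome chains such as gut
    microbiota, immune-cell phenotypes and disease risk. A synthetic
    summary-statistics generator with known causal structure supports
    calibration and validation without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
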