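Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization (MR)
    from GWAS summary statistics: reading and validating association tables,
    allele harmonization between exposure and outcome studies, selection of
    independent genome-wide-significant instruments by greedy LD clumping
    with proxy substitution, the standard estimator suite (Wald ratio,
    inverse-variance-weighted meta-analysis, MR-Egger regression, simple and
    weighted median, multivariable MR), instrument-strength and
    leave-one-out diagnostics, and study-level orchestration over many
    exposures and outcomes with Bonferroni-corrected association calls.
    Includes a summary-level GWAS simulator with known causal effects,
    horizontal pleiotropy and LD structure, so every stage can be verified
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
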