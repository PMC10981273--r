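Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection (p-value thresholds,
    outcome-association exclusion, LD clumping, MR-PRESSO outlier screening,
    F-statistics, Steiger filtering), six causal estimators (Wald ratio,
    fixed- and random-effects inverse-variance weighting, maximum likelihood,
    MR-Egger, weighted median, weighted mode), a sensitivity battery
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out, Steiger
    directionality), Benjamini-Hochberg FDR tiering, multivariable MR, and
    two-step mediation with delta-method confidence intervals. A synthetic
    three-trait (exposure, mediator, outcome) GWAS summary-statistics
    generator with known ground truth exercises every stage without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
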