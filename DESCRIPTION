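Package: faersignal
Title: Disproportionality Signal Detection for FAERS Drug-Induced
    Movement Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection of
    drug-induced movement disorders (DIMD) in FDA Adverse Event Reporting
    System (FAERS) quarterly extracts: ingestion of the "$"-delimited ASCII
    dialect with two-stage case deduplication and field normalization,
    MedDRA preferred-term case definition, per-drug two-by-two contingency
    tables scored by four disproportionality algorithms (reporting odds
    ratio, proportional reporting ratio with chi-squared, the Bayesian
    confidence propagation neural network information component, and the
    DuMouchel-type empirical Bayes geometric mean), combined signal
    thresholds with Fisher/Bonferroni screening, and a LASSO-then-logistic
    risk-factor model with ROC evaluation. A bundled synthetic FAERS
    generator with known ground-truth odds multipliers makes every stage
    testable without downloading FAERS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    glmnet,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
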