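Package: synthehr
Title: Generation and Multi-Faceted Validation of Synthetic Longitudinal Diabetes Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating and auditing synthetic longitudinal electronic
    health records for diabetes-anchored cohorts. Provides a ground-truth cohort
    simulator with a bias injector, a dual adversarial autoencoder for sequences
    of set-valued visits, a refinement pipeline for raw generated cohorts, and a
    validation suite covering statistical fidelity (boundary/category adherence,
    Kolmogorov-Smirnov and total-variation complements, correlation and
    contingency similarity, sliced Wasserstein distance, temporal co-occurrence
    correlation), privacy (new-row synthesis, attribute-disclosure protection,
    zero-knowledge membership inference), algorithmic sex-bias forensics,
    trajectory plausibility via dynamic time warping, and train-synthetic/
    test-real predictive utility with a cyclic-boosted additive classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    glmnet,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
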