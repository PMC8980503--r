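Package: rehabite
Title: Heterogeneous Treatment Effects of Health Service Use After Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing how post-discharge health-service use relates to
    quality-of-life, psychological-wellbeing, global-function and participation
    outcomes after acquired brain injury. Provides scoring for the EQ-5D-5L,
    DASS-21, MPAI-4, SPRS-2 and Service Obstacles Scale instruments, multiple
    imputation by chained equations with predictive mean matching, a from-scratch
    Bayesian Additive Regression Trees (BART) sampler for continuous outcomes,
    and counterfactual estimation of individual, conditional-average and average
    treatment effects of discretized service-use variables, with posterior
    credible-interval summaries and a heterogeneity screen. A synthetic cohort
    generator with known injected effects supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
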