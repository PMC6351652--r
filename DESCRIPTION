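Package: topicPheWAS
Title: Topic-Based Phenome-Wide Association for EHR Diagnostic Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for phenome-wide association (PheWAS) using probabilistic
    topic models over electronic health record diagnostic codes. Rolls up
    ICD-9 billing codes to PheWAS codes with a prevalence filter, fits a
    latent Dirichlet allocation model to the subject-by-code count matrix
    by collapsed Gibbs sampling, tests each topic membership score for
    association with a single genetic variant (additive allelic linear
    regression, adjusted for principal components) separately per
    genotyping wave, pools waves by inverse-variance-weighted fixed-effects
    meta-analysis with a Bonferroni experiment-wide threshold, and follows
    up significant topics at the individual-code level with logistic
    regression. A fully specified synthetic genotype-plus-EHR cohort
    generator with a planted genotype-to-topic effect supports end-to-end
    verification without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml,
    vcfR,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
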