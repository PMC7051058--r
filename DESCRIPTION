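Package: ageGWIS
Title: Genome-Wide Age-by-Genotype Interaction Analysis for Binary
    Treatment Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide interaction studies (GWIS) of a binary
    treatment-response outcome with a continuous exposure such as age.
    Provides synthetic cohort simulation under a logistic
    gene-by-environment generative model, variant quality control
    (minor allele frequency, call rate, Hardy-Weinberg exact test,
    imputation quality) with principal-component covariates, fast
    per-variant logistic interaction regression with Wald inference,
    two-stage discovery/replication filtering with direction-concordance
    gating and sample-size-weighted Z-score joint analysis, candidate-gene
    proxy annotation, and an empirical power calculator for
    gene-by-environment interactions with binary outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
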