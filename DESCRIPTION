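Package: MethylTL
Title: Methylation-Based Telomere Length Estimation and Validation Toolkit
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains, applies and validates linear CpG clocks that estimate
    telomere length (in kilobases) from Illumina-style DNA methylation beta
    values. Implements elastic-net clock training with the lambda.1se
    cross-validation rule, application of arbitrary coefficient tables to
    beta matrices, age adjustment of the resulting estimates, per-cohort
    association statistics (biweight midcorrelation, covariate-adjusted
    linear models, Cox proportional hazards with sandwich standard errors),
    Stouffer and inverse-variance fixed-effect meta-analysis with Cochran Q
    heterogeneity, and hypergeometric enrichment of clock CpGs near
    chromosome ends. A seeded synthetic-cohort generator with planted
    telomere-associated CpGs, covariate structure and survival outcomes
    makes the whole pipeline testable without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    survival,
    sandwich,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
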