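Package: depredict
Title: Predicting Depression Diagnosis, Severity and Treatment Response
    from Longitudinal Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based electronic phenotyping of depression from
    longitudinal EHR event streams (ICD-9 codes, annotated clinical-note
    terms with negation and family-history flags, drug-ingredient
    mentions), exact case-control matching on age and visit-history
    length, prediction-horizon truncation, and L1-penalized logistic
    models for predicting a future diagnosis of depression, baseline
    severity (PHQ-9), and response to treatment, together with an
    information-gain screen and interaction-term logistic regression for
    treatment moderators. Includes a seeded synthetic-EHR generator that
    emulates the statistical structure every stage assumes, so the whole
    pipeline is testable without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'depredict-package.R'
    'utils.R'
    'terminology.R'
    'simulate.R'
    'phenotyping.R'
    'features.R'
    'io.R'
    'outcomes.R'
    'roc.R'
    'prediction.R'
    'moderators.R'
    'pipeline.R'
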