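Package: ehrnet
Title: Feature Selection and Mutual-Information Comorbidity Networks for
    EHR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An inference pipeline for electronic-health-record (EHR)
    cohorts with a dichotomous disease outcome, built around type 2
    diabetes phenotyping. Provides a seeded synthetic-cohort generator
    with planted comorbidity blocks and ground truth, curation rules
    (BMI categorisation, age filtering, missingness-based variable
    exclusion), two feature-selection arms (random-forest importances
    with a boxplot-notch cutoff, and L1-penalised logistic regression
    tuned by cross-validation), Wald z-score node scoring, a
    mutual-information network over the case subpopulation with
    Monte-Carlo permutation edge significance, and fast-greedy
    modularity community detection with an exhaustive small-graph
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
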