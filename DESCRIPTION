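Package: pathboost
Title: Variant Pathogenicity Scoring with Confidence-Weighted Gradient-Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for training and evaluating a variant
    pathogenicity classifier on genome-annotation features. Curates labelled
    variant sets from heterogeneous sources (deduplication, conflict removal,
    dominant-gene carrier filtering, confidence-tier sample weights), fits a
    reusable feature-encoding schema (top-level one-hot encoding of categorical
    annotations, fixed-value imputation of numerical annotations, population
    allele frequency with zero default), trains a sample-weighted gradient
    boosted tree classifier with randomized hyperparameter search and early
    stopping, selects a recall-constrained decision threshold, evaluates scores
    with bootstrap AUC and allele-frequency/consequence stratification, and
    ranks causal variants in solved exomes. A synthetic-data module generates
    annotated variant sets with known signal strength so the whole pipeline is
    testable against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
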