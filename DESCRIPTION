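Package: tissuehet
Title: Detecting Tissue Heterogeneity in Bulk Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of tissue heterogeneity - expression
    signal from cells of origins other than the annotated tissue - in bulk
    gene expression corpora. Provides a per-sample Wilcoxon-Mann-Whitney
    gene-set enrichment engine, Gini-index based generation and
    cross-validation of tissue-specific gene signatures, controlled-vocabulary
    tissue harmonization and corpus filtering, a five-step heterogeneity
    detector (false-discovery-rate screening, robust-line exclusion of
    correlated signature pairs, moderate/severe classification), per-tissue
    prevalence estimates with bootstrap confidence intervals, and a seeded
    synthetic-corpus generator with full ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    Matrix
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
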