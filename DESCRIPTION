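Package: evoboost
Title: Multiobjective Evolutionary Feature Selection and Hyperparameter
    Tuning for Gradient-Boosted Biomarker Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A niched multiobjective evolutionary wrapper for biomarker
    discovery on imbalanced tabular biomedical data. Candidate solutions
    encode a binary feature mask, a filter-method gene (ANOVA F, Wilcoxon
    rank sums, joint mutual information, or minimum-redundancy
    maximum-relevance prescreens) and seven hyperparameters of an extreme
    gradient boosting classifier. Solutions are scored by stratified
    cross-validation on ten maximized objectives (eight imbalance-aware
    classification metrics plus two model-simplicity metrics), ranked into
    Pareto fronts, and diversified by fitness sharing over a dual
    genotype distance. The final dominant front yields a best-compromise
    model, hard and soft majority-voting ensembles with degenerate-model
    exclusion, and the selected feature panel (biosignature). Includes a
    synthetic-data module emulating expression-like and questionnaire-like
    cohorts for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
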