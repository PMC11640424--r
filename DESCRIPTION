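Package: thermoTLB
Title: Rank-Based Classification of Biofluid DSC Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for thermal liquid biopsy: preprocessing of differential
    scanning calorimetry (DSC) thermograms of biological fluids (baseline
    correction, interpolation to a uniform temperature grid, area
    normalization, per-degree feature extraction), construction of
    temperature-pair ordering features with a top-scoring-pairs statistic,
    L1-penalized logistic scoring with a sign decision rule, and diagnostic
    evaluation (confusion metrics, ROC/AUC with bootstrap confidence
    intervals, Wilcoxon rank-sum comparisons). Includes a synthetic
    thermogram-cohort generator so the full pipeline can be exercised and
    calibrated without access to clinical samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
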