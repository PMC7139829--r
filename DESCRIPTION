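Package: diliqsar
Title: QSAR Classification of Drug-Induced Liver Injury with Nested
    Cross-Validation and Ensemble Stacking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating binary hepatotoxicity
    (drug-induced liver injury, DILI) classifiers from molecular-descriptor
    tables in the layout of the FDA DILIrank list. Provides a
    SummarizedExperiment-derived container for compounds-by-descriptor data,
    the standard QSAR preprocessing filters (quasi-constant and
    auto-correlation removal, z-scoring with capping of extreme values),
    rescaled Gower dissimilarity for chemical-diversity assessment, a registry
    of univariate feature-selection filters, leakage-safe nested
    cross-validation over pluggable learners with random hyperparameter
    search, model selection on balanced accuracy and positive predictive
    value, y-randomization, ensemble stacking (majority vote, pooled
    probabilities, meta-models), virtual screening of external compound
    libraries, and outlier / applicability-domain diagnostics (isolation
    forest, subspace outlier detection, kNN distance thresholds, INFLO, COF).
    A synthetic-data generator emulates the statistical structure of
    descriptor tables so the whole pipeline is testable without commercial
    descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    class,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    randomForest,
    rpart
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr
biocViews: Classification, Cheminformatics, Pharmacogenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
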