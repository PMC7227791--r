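Package: mcfsel
Title: Monte Carlo Feature Selection and Incremental Feature Selection
    for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks genes in a two-class expression matrix by Monte Carlo
    feature selection: many small random feature subsets, an ensemble of
    information-gain decision trees per subset, and a relative-importance
    score that aggregates weighted-accuracy-scaled information gain over
    all tree nodes splitting on a gene.  Incremental feature selection
    with leave-one-out cross-validated SVM or decision-tree classifiers
    then picks an optimal biomarker panel from the ranking, followed by
    hypergeometric over-representation analysis against gene-set
    collections and heatmap-style clustering reports.  Includes a
    planted-signal expression simulator with known ground truth for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
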