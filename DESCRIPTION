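Package: phosphoresponse
Title: Acute Phosphoproteomic Drug Perturbation Analysis and Network-Based
    Combination Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for acute (1-hour) phosphoproteomic drug
    perturbation screens in cancer cell panels. Normalizes multiplexed
    bead-assay measurements against GAPDH loading controls and DMSO vehicle
    wells into signed perturbation profiles; predicts drug-sensitivity
    quartiles from those profiles with random-forest and elastic-net models
    under Monte-Carlo cross-validation; computes the environmental
    perturbation score (EPS), a protein-protein interaction neighborhood
    integration of absolute phosphoprotein changes used to rank tractable
    co-targets and nominate synergistic drug combinations; scores two-drug
    dose grids by Bliss independence; and validates EPS-synergy concordance
    with Mann-Whitney rank-bias tests and permutation null simulations. A
    synthetic-cohort generator with recorded ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    glmnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
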