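Package: adrnet
Title: Adverse Drug Reaction Prediction from Drug-Target Expanding
    Networks and Gene Ontology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A systems-pharmacology framework for predicting an adverse
    drug reaction (ADR) class of a drug from its protein targets. Drug-target
    facts are enriched by one-level expansion in a star-rated protein-protein
    interaction network and by Gene Ontology biological-process annotations
    rolled up or thresholded at a chosen term level. Features are screened by
    Fisher's exact or Wilcoxon rank-sum tests, class imbalance is handled by
    majority-class partition ensembling, and models (RBF-kernel SVM, logistic
    regression) are evaluated by repeated stratified 10-fold cross-validation
    with AUC, accuracy, sensitivity and specificity. Includes a synthetic-data
    generator with a planted, network-mediated toxicity mechanism so the whole
    pipeline can be exercised without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
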