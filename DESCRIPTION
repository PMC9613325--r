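Package: milknet
Title: Differential Co-Abundance Network Analysis for Label-Free Milk
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free (LFQ) human-milk proteome
    studies with a 2x2 mother/child allergy design: group-validity
    filtering and left-censored (MNAR) imputation of missing LFQ
    intensities, nonparametric univariate screening (Kruskal-Wallis,
    Dunn's post-hoc, Benjamini-Hochberg), unsupervised and supervised
    exploration (PCA, random-forest classification with permutation
    tests), probabilistic correlation network inference (PCLRC with CLR
    background correction), node connectivity and differential
    connectivity with permutation inference, simultaneous component
    analysis of several group networks (COVSCA), and two-list
    hypergeometric overrepresentation of annotation keywords.  Includes
    a synthetic-data generator that plants known correlation structure,
    hubs, abundance shifts and left-censoring so every stage can be
    tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
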