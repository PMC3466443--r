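Package: ScaffoldScreen
Title: Scaffold Enrichment and Cost-Sensitive Classification for
    Imbalanced Small-Molecule Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mining heavily imbalanced high-throughput screening data for
    active chemotypes: PubChem-style activity-score banding and
    counter-screen curation, PowerMV-family 2D descriptors (pharmacophore
    pair fingerprint bits, Burden-matrix eigenvalue descriptors and
    whole-molecule properties), cost-sensitive Naive Bayes and Random
    Forest classification with a false-positive-capped misclassification
    cost search, confusion-matrix and ROC evaluation, maximum common
    substructure (MCS) scaffold clustering of actives, and chi-square
    scaffold enrichment statistics. Includes a synthetic bioassay
    generator with planted scaffolds so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    ChemmineR,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
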