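Package: morbnet
Title: Network-Based Prediction of Morbid and Druggable Human Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide prediction of morbid (disease-causing) and druggable
    human genes from systems-level data. Builds an integrated multi-layer gene
    network from protein physical, metabolic and transcriptional-regulatory
    interactions (with currency-metabolite removal for the metabolic layer),
    computes twelve per-gene topological features plus tissue-expression and
    subcellular-localization attributes, trains a bagged seven-member voting
    tree ensemble on balanced positive/unlabeled datasets with shuffled-label
    null controls, scores all genes with per-gene exact Wilcoxon signed-rank
    significance, and extracts interpretable cellular rules from gain-ratio
    decision trees. Includes a synthetic data generator emulating the joint
    structure of the input data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    rpart,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
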