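Package: lncsim
Title: LncRNA Functional Similarity from Disease Semantic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes functional similarity between long non-coding RNAs
    (lncRNAs) from their associated disease groups, using two directed-acyclic-
    graph based disease semantic similarity models over a hierarchical disease
    vocabulary (MeSH Category C style tree numbers): a decay-factor
    contribution model and a DAG-frequency (information-content style) model.
    Pairwise lncRNA similarity is the best-match average of the semantic
    similarities of the two associated disease groups. The package also builds
    Gaussian interaction-profile kernel similarities and rank-correlation
    expression similarities, combines them with the functional similarity, and
    scores all lncRNA-disease pairs with a Laplacian-regularized least-squares
    predictor. A leave-one-out cross-validation harness with rank-based
    ROC/AUC, a synthetic-data generator for clustered association structure,
    and a small command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
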