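Package: iegdecoder
Title: Decoding Recent Experience from Immediate-Early Gene Induction Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding the identity of a recent salient experience
    from multiplexed qPCR measurements of immediate-early gene induction
    across brain structures. Converts raw Ct tables to delta-delta-Ct fold
    inductions against a global reference-gene set and matched control
    groups, assembles per-animal gene-by-structure feature vectors, ranks
    candidate marker genes by frequency and consistency of induction,
    classifies experience labels with a leave-one-out k-nearest-neighbor
    decoder, validates decoding with label-permutation empirical p-values,
    and ranks features by Random-KNN support, random-forest mean decrease in
    Gini impurity, and descriptive CART trees. A synthetic-data module
    generates Ct-level and feature-level datasets with known ground truth so
    every stage of the pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    randomForest,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
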