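Package: MuscleCrosstalk
Title: Cross-Tissue Cytokine-Pathway Crosstalk Networks from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links gene expression of secreted inflammatory mediators in lung
    to pathway-level transcriptional activity in skeletal muscle. Implements
    present-call filtering, SAM-style two-class permutation differential
    expression with FDR control, EASE-score pathway over-representation with
    direction annotation, principal-component pathway activity indices,
    permutation-tested Spearman bipartite network inference with Cytoscape
    export, cross-species pathway-signature sensitivity/specificity overlap
    with Jaccard similarity and average-linkage clustering, and a serum
    validation arm (KNN imputation, Z-scoring, Mack-Skillings two-factor rank
    test, serum-muscle correlation ranking and pre-ranked GSEA). Ships a
    synthetic cohort generator with planted effects and ground truth for
    parameter-recovery testing, and a seeded end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    yaml,
    jsonlite,
    MASS
Suggests: testthat (>= 3.0.0), fgsea, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
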