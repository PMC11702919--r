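Package: fapnet
Title: Network Analysis of Activity-Dependent Regulators of Muscle
    Progenitor Adipogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A network-medicine toolkit for identifying activity-dependent
    regulators of fibro-adipogenic progenitor (FAP) adipogenesis from
    transcriptomic response profiles. Implements count and intensity
    filtering, CPM/TMM normalization, moderated-t differential expression,
    preranked and single-sample gene set enrichment analysis (GSEA/ssGSEA)
    with leading-edge extraction, weighted gene co-expression network
    construction (soft thresholding, topological overlap, module detection,
    eigengenes, hub genes), random-walk-with-restart network propagation
    (GSEA-guided forward, backward, and bidirectional "squeeze" variants),
    and downstream statistics (PC1 condition-separation scores with
    leave-one-out robustness, exact Mann-Whitney U tests, percentage
    rejuvenation). A synthetic-data generator with planted co-expression
    modules, a planted hub gene and a planted mediator pathway makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    fgsea,
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
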