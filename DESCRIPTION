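Package: DEGnet
Title: Multi-Stage Expression, Network and Association Screening for
    Case-Control Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a multi-stage biomarker
    discovery workflow for small case-control expression studies, as applied
    to sporadic amyotrophic lateral sclerosis: differential expression with
    fold-change and adjusted-p screening, tissue/organ-specific expression
    calling against an expression atlas, protein-protein interaction network
    construction with MCODE-style dense-module detection and five-centrality
    hub consensus (MCC, Degree, DMNC, MNC, clustering coefficient),
    over-representation and pre-ranked gene-set enrichment, consensus miRNA
    target selection with tripartite ceRNA network assembly, ROC and
    Kaplan-Meier biomarker evaluation, and case-control SNP allele association
    with risk-ratio confidence intervals. Every input can be simulated with
    planted ground truth, so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival,
    pROC,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
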