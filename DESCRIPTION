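Package: mirdynet
Title: Dynamic miRNA-TF-Target Network Analysis for Time-Series Stress
    Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and analysing dynamic miRNA-TF-target
    regulatory networks from replicated treatment/mock time-series expression
    data. Calls per-time-point differential expression and assigns each
    responsive entity one of eleven temporal response classes; assembles a
    tripartite regulatory network (TF-target, TF-miRNA, miRNA-target edges),
    derives a per-time-point multilayer dynamic network, and scores node
    rewiring; performs an induced-subgraph census of the four three-node
    motif shapes (feed-forward loop, fan-out, cascade, fan-in) with role
    typing, degree-preserving randomization enrichment, persistence,
    expression coherence, crosstalk and clustering-coefficient statistics;
    builds weighted co-expression modules and the XYZ/XZ co-module ratio
    statistic across motif classes; and profiles primary-miRNA expression in
    single-cell data via cell quality filtering, per-(cell type, condition)
    pseudobulk aggregation, differential pri-miRNA calling, and detection of
    cell-type-unique miRNA feed-forward loops. A synthetic-data module
    generates expression tables, edge lists and sparse cell count matrices
    with planted ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
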