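Package: coexdiff
Title: Differential Co-Expression Network Analysis Across Diagnostic States
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds condition-specific signed Pearson co-expression networks
    from blood microarray expression profiles labelled with diagnostic states
    (normal condition, mild cognitive impairment, Alzheimer's disease).
    Probes are filtered in two stages -- a coefficient-of-variation and
    intensity filter on de-normalized linear intensities, then a one-way
    ANOVA across diagnostic groups -- before pairwise Pearson correlation
    matrices are thresholded into positive and negative networks per state.
    Networks are compared with a per-node rewiring score (variance of a
    node's adjacency across states) and with consensus differential-edge
    inference against a reference state. A synthetic-data generator plants
    mean shifts, correlation blocks and known rewired nodes so the whole
    pipeline is testable without controlled-access clinical data. Edge
    tables, GraphML and SIF exports are Cytoscape-compatible.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
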