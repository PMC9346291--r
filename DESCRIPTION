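Package: orthoconv
Title: Convergent Ortholog Expression Analysis Across Plant Growth Forms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative-transcriptomics pipeline for detecting convergent
    gene expression across species groups that share a growth form. Starting
    from per-species tabular sequence-search hit tables against a single
    reference proteome, the package filters hits by e-value and query
    coverage, resolves one best reference ortholog per transcript, and builds
    a species-by-ortholog presence matrix. Orthologs are then classified into
    a common core, group-exclusive sets at each convergence level (present in
    exactly k focal-group units and no background unit), and a group-absent
    (co-downregulated) set. Classified sets seed first/second-shell
    subnetwork extraction from STRING-style weighted interaction edge lists,
    with sector annotation, network merging, hub ranking, and graph export.
    Over-representation of annotation terms is tested with an exact
    hypergeometric upper tail and Benjamini-Hochberg correction. A synthetic
    community generator with planted ground truth (core, exclusive, absent,
    hub, enriched term) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'convergence.R'
    'enrichment.R'
    'hit-tables.R'
    'interactome.R'
    'orthoconv-package.R'
    'pipeline.R'
    'synthetic-community.R'
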