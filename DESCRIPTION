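Package: evcargo
Title: Extracellular Vesicle miRNA Cargo Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for microRNA cargo of skeletal-muscle extracellular
    vesicles profiled by pooled small RNA sequencing. Implements trimmed mean of
    M-values (TMM) normalization and counts-per-million filtering from first
    principles, fold-change based up/down classification across pairwise group
    comparisons without replicates, aggregation of miRNA-to-mRNA target
    interactions from multiple evidence databases, muscle-keyword-filtered
    hypergeometric Gene Ontology biological-process enrichment stratified by
    regulatory direction (suppressed versus derepressed), and hub-gene
    connectivity scoring. A seeded synthetic-data generator emulates the study
    design (pooled single-column groups, heavy-tailed abundance with a dominant
    myomiR, planted differential cargo, bipartite target maps with hub genes)
    so every stage is testable without access to sequencing files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
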