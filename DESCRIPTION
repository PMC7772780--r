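Package: cageatlas
Title: CAGE Promoter Atlases, Expression-Breadth Classes and 5'UTR Translatability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds promoter atlases from multi-tissue CAGE (cap analysis of
    gene expression) transcription start site data. Raw tag counts are
    normalized against a reference power-law distribution, clustered into
    per-sample tag clusters with interquantile widths, aggregated into
    cross-tissue consensus promoters, assigned to gene models, and classified
    by genomic position and cross-tissue expression breadth (non-ubiquitous,
    ubiquitous-uniform, ubiquitous-nonuniform). Companion tools reconstruct
    spliced 5'UTR leaders and census their upstream open reading frames, GC
    content and splice-junction canonicity, and build neighbor-joining trees
    with bootstrap support from multiple sequence alignments. A synthetic-data
    generator emulates multi-tissue CAGE experiments with planted ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
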