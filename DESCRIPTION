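Package: miratlas
Title: Cross-Species miRNA Annotation Harmonization and Tissue-Enrichment
    Atlas Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a harmonized microRNA locus annotation for a target
    genome from mature miRNA sequence sets of several species (consolidate,
    place with zero mismatches, drop promiscuous mappers, merge co-located
    hits), quantifies small-RNA read alignments against those loci under a
    minimum-overlap rule with reads-per-million normalization, classifies
    tissue-enriched (TE) and highly tissue-enriched (HTE) miRNAs with
    Wilcoxon rank-sum tests and Benjamini-Hochberg FDR control, performs
    Spearman sample-correlation quality control and reference-miRNA
    stability scoring, and implements the delta-Ct qPCR workflow
    (replicate censoring and averaging, reference normalization,
    cross-platform correlation, serum biomarker-panel assessment against
    clinical chemistry). A synthetic-data generator with planted ground
    truth emulates the full tissue-atlas study design so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    igraph,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
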