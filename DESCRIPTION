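Package: methylscape
Title: Whole-Genome Bisulfite Methylome Analysis for Mosaic Diatom-Like Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for whole-genome bisulfite methylomes with a
    large-scale binary (mosaic) methylation architecture, as seen in centric
    diatoms: per-context (CG/CHG/CHH) methylation statistics, gene-body
    methylation classification, sliding-window segmentation into hyper- and
    hypomethylated domains with repeat overlap, cross-condition comparison,
    integration of methylation status with expression (FPKM), taxonomic-origin
    methylation enrichment with a permutation test, and consensus gene-model
    selection with genome statistics. Includes a seeded synthetic methylome
    generator with closed-form expected summaries for calibration and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
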