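Package: transgeno
Title: RNA-Seq-Based Genotyping of Inbred Crop Strains: Regions, Filters,
    Markers and Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream toolkit for reference-based RNA-Seq genotyping of
    inbred crop germplasm. Builds merged transcribed regions (gene locus
    spans plus fixed flanks) from GFF3 gene models and emits BED/FASTA;
    applies a reliability and marker-suitability filter cascade (per-call
    read depth, singleton, replicate-conflict, multi-allele and
    neighbour-window rules) to a merged multi-sample VCF; computes genotype
    matrix analytics (pairwise polymorphism counts, group-wise minor allele
    frequency and missingness filters, polymorphism-free gap scanning); and
    evaluates genotype concordance between replicate libraries and between
    RNA-Seq and amplicon resequencing platforms. A deterministic
    synthetic-data generator with a planted-truth manifest makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
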