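Package: txpolish
Title: Post-Assembly Polishing, Annotation Transfer and Expression
    Partitioning for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the post-assembly computation stack of a
    de novo plant transcriptome project: paired-end read quality trimming
    (sliding-window rule, adapter clipping, orphan-pair dropping), contig-level
    adapter detection and clipping by word-4 seed-and-extend alignment,
    two-stage contamination triage against a reference genome and a general
    nucleotide database, length filtering, six-frame ORF enumeration with
    representative-peptide selection, reciprocal-best-hit annotation transfer,
    Nx and expression-weighted ExNy assembly statistics, and tissue
    presence/absence Venn partitioning. A seeded synthetic-data generator
    produces fixtures with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
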