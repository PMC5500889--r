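Package: cimscall
Title: Single-Nucleotide m6A Mapping from miCLIP Crosslink-Induced Mutation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls N6-methyladenosine (m6A) sites at single-nucleotide
    resolution from miCLIP sequencing data via crosslink-induced mutation
    sites (CIMS). Implements barcode demultiplexing and UMI-based PCR
    duplicate collapsing, strand-aware C-to-T transition pileup with m/k
    mutation-ratio filtering, adenosine-context and SNP filters, peak
    clustering of unique tags, DRACH/RAC motif enrichment statistics,
    rescaled 5'UTR/CDS/3'UTR metagene profiles, per-gene intronic site
    counting with max-over-isoform summarisation, and miCLIP versus
    mRNA-seq FPKM enrichment. Includes a synthetic miCLIP read simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    data.table,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
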