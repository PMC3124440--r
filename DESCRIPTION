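Package: snvmine
Title: SNV Calling and Marker Selection from Transcriptome Read Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines single nucleotide variants (SNPs and short indels) from
    reads mapped to a reference transcriptome of unigenes. Provides native
    read cleaning (quality trimming, adaptor removal, length filtering) with
    cleaning statistics, pileup construction from SAM/BAM with read-group
    accession and library labels, SNV calling based on a three-best-read
    allele quality score with mapping-quality exclusion, a suite of nine
    marker-selection filters written into VCF (allele frequency, variable
    region, unigene uniqueness, intron/end/neighbour distances, CAPS
    restriction-site detection, marker kind, library frequency), and
    accession-count based polymorphism estimation with polymorphic
    information content (PIC). A deterministic synthetic-data generator
    produces unigenes, planted per-accession variants, platform-specific
    reads and alignments together with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    BiocGenerics,
    data.table,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
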