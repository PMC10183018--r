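Package: zcrtools
Title: Zero-Coverage Regions, Presence/Absence Variation and Composite
    dN/dS from Multi-Sample Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects zero-coverage regions (ZCRs) in per-sample read
    coverage tracks after masking assembly gaps, flags genes whose exons
    overlap ZCRs, summarises ZCR burden by gene set, computes per-sample
    variant densities and zygosity partitions from hard-filtered variant
    calls, classifies coding single-nucleotide variants as synonymous or
    non-synonymous on the canonical transcript to obtain composite
    per-gene dN/dS ratios with positive-selection calling, performs
    hypergeometric gene-set over-representation testing with
    Benjamini-Hochberg correction, and detects discordant and
    complementary presence/absence haplotype patterns across samples.
    Ships a synthetic multi-sample study generator with planted
    deletions, genotype structure and selection classes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
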