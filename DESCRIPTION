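Package: splicord
Title: Allele-Specific Splicing Order and Nascent RNA Maturation from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of allele-specific pre-mRNA maturation from spliced
    long-read (direct RNA nanopore) alignments of chromatin-associated RNA.
    Classifies the excision status of every intron on every read from its
    CIGAR string, assigns reads to parental haplotypes using phased
    heterozygous SNPs, computes multi-intron splicing-order scores per
    allele, calls allele-specific splicing orders with contingency tests and
    a replicate-calibrated Euclidean-distance threshold, and compares
    poly(A) tail lengths, 3'-end positions and transcript abundance between
    alleles. Includes a read-level simulator with known per-allele
    splicing-order mixtures for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
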