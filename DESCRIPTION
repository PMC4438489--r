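Package: cismotifs
Title: Genome-Wide Characterization of DNA Sequence Motifs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize a DNA sequence motif genome-wide:
    likelihood-ratio scanning of a position-specific probability matrix
    against a k-th order Markov background, count-matched cutoff selection,
    overlap deduplication, single-linkage clustering of motif sites,
    promoter-enrichment statistics (fold enrichment, implied FDR,
    two-proportion Z-tests), matched genomic control regions, permuted-matrix
    and random-site null controls, phylogenetic-conservation profiling, and
    DNase I hypersensitivity normalization and comparison. Includes a
    synthetic-genome generator with planted motif structure for end-to-end
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
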