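Package: plastcomp
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for pairwise comparative analysis of plastid
    (chloroplast) genomes: detection of the inverted-repeat pair and the
    quadripartite LSC/IRa/SSC/IRb partition, MISA-style microsatellite and
    REPuter-style maximal-repeat censuses, SNP/indel calling and sliding-window
    divergence from pairwise alignments, codon-usage statistics (RSCU, CAI,
    Wright's ENC, GC by codon position, neutrality regression), Nei-Gojobori
    Ka/Ks estimation, C-to-U RNA-editing site calling with per-site editing
    efficiency, long-read classification of the two SSC-orientation structural
    haplotypes, and genus-specific indel analysis of labelled gene alignments.
    A synthetic-data module generates plastomes, diverged sister genomes, long
    reads and per-replicate pileups with known truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
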