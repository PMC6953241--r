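Package: grasskit
Title: LTR Insertion Dating, Ks-Based WGD Dating, QTL-seq/BSA Scans and
    Windowed Population-Genetic Statistics for Grass Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for common comparative- and population-genomic
    computations in forage-grass genome projects: dating long terminal repeat
    (LTR) retrotransposon insertions from 5'/3' LTR divergence via the
    Jukes-Cantor correction and a molecular clock; dating whole-genome
    duplications from the synonymous-distance (Ks) distribution of duplicate
    coding-sequence pairs using Nei-Gojobori (1986) counting; a bulked
    segregant analysis (QTL-seq) scan built on informative-SNP
    prioritization, per-pool SNP indices, sliding-window delta(SNP index)
    and a SNP-density-transformed delta statistic with candidate-region and
    candidate-gene calling; and windowed nucleotide diversity, Hudson FST
    and linkage-disequilibrium r2 scans. Includes simulators (LTR pairs
    under a per-site Jukes-Cantor clock, synonymous-only CDS divergence, an
    F1 biparental pool-seq cross with one causal locus, and Balding-Nichols
    two-population panels) that carry ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    ape,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
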