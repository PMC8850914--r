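Package: pedscan
Title: Pedigree-Based Candidate Gene Discovery for Crop Breeding Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing the genetic basis of trait improvement through
    a breeding pedigree from resequencing data. Implements windowed nucleotide
    diversity and low-diversity (sweep) block calling, an identity-by-descent
    sliding-window scan that attributes a descendant's genome to its ancestors,
    codon-level classification of SNP functional effects, gene-level haplotype
    construction with haplotype-trait association and two-locus synergy
    decomposition, co-expression hub-consensus ranking with a differential
    expression screen, and trait gene-set intersection and pleiotropy analysis.
    Includes a deterministic pedigree simulator with recombination and planted
    effect/expression structure for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
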