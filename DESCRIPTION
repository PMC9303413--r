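Package: seedasm
Title: Seeded Iterative Local Assembly of Targeted Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Targeted local assembly by iterative cycles of read retrieval
    and de novo assembly. A nucleotide or protein seed sequence recruits
    matching reads from an indexed read store using a BLAST-like
    seed-and-extend local aligner with bitscore and e-value statistics;
    recruited reads (optionally fragmented long reads) are assembled with a
    built-in greedy overlap-layout-consensus assembler; contigs matching the
    original seeds are carried forward, optionally polished by
    pileup-majority consensus from accurate short reads, and used to recruit
    further reads until a stopping criterion fires. Includes simulators for
    multi-allele loci, short paired-end and long noisy reads with
    substitution, indel and homopolymer run-length error channels, and
    evaluation utilities for contig accuracy, growth trajectories, locus
    calling and primer anchor scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
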