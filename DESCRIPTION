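Package: barcodetrack
Title: De Novo Consensus Barcodes from Noisy Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A self-contained pipeline that reconstructs high-accuracy DNA
    barcode sequences (for example the ~658 bp mitochondrial COI marker) from
    noisy nanopore-style amplicon reads.  Reads are demultiplexed by dual end
    tags, filtered by length, clustered at 70% identity to drop contaminants
    such as nuclear mitochondrial insertions (NUMTs), multiply aligned with a
    partial-order aligner, reduced to a plurality draft consensus, polished by
    pileup voting with homopolymer run-length re-estimation, and combined over
    seeded iterations by a majority rule.  A read simulator with a
    homopolymer-aware indel error model makes every stage testable against a
    known reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
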