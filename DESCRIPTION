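Package: ontbench
Title: Accuracy Assessment of Nanopore Basecalls Against a Trusted Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Evaluates basecalled long-read sets against a trusted reference
    genome. Computes per-read BLAST identity with the standard edge rules
    (reads aligned over less than half their length, or missing from the
    basecaller output, count as 0% identity) and median/qscore summaries;
    builds a reference-guided consensus by replacing reference spans with
    read sequence and polishing with majority-vote pileup rounds, iterated
    over shuffled reads and rotated reference starts with a final
    meta-assembly; measures consensus accuracy on 10 kbp chunks; and
    classifies consensus errors by reference context (Dcm CCAGG/CCTGG motif,
    homopolymer insertion/deletion, plain insertion/deletion/substitution).
    Includes a seeded banded affine-gap aligner and a synthetic-data
    generator with random and systematic (motif- and homopolymer-linked)
    error channels plus a ground-truth ledger for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
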