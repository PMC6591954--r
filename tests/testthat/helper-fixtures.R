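# fixtures are generated in code: random sequences, mutated copies with a
# known edit budget, and small simulated data sets

random_seq <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# apply up to n_edits random single-base edits (sub/ins/del) to a sequence
mutate_seq <- function(seq, n_edits) {
  ch <- strsplit(seq, "")[[1]]
  for (k in seq_len(n_edits)) {
    op <- sample(3, 1)
    p <- sample(length(ch), 1)
    if (op == 1) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    } else if (op == 2 && length(ch) > 10) {
      ch <- ch[-p]
    } else {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = p)
    }
  }
  paste0(ch, collapse = "")
}

# substrings of a reference as error-free reads with even tiling coverage
tiling_reads <- function(ref_seq, read_len, step) {
  L <- nchar(ref_seq)
  starts <- seq(1, max(1, L - read_len + 1), by = step)
  seq_tbl(sprintf("t%03d", seq_along(starts)),
          substring(ref_seq, starts, pmin(starts + read_len - 1, L)))
}

# Biostrings full-DP score for the same semi-global problem (query global,
# target end gaps free); the independent alignment oracle
oracle_score <- function(query, target, scoring = scoring_scheme()) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                 mismatch = -scoring$mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    query, target, type = "global-local", substitutionMatrix = sm,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend))
}
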