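# Reference-guided consensus: replace reference spans with read sequence,
# polish with majority-vote pileup rounds, and iterate with shuffled reads
# and rotated reference starts followed by a final meta-assembly.
#
# The polisher is a column-wise pileup plurality vote with insertion events
# keyed to the junction's right-flanking draft position. It is a
# deterministic, dependency-free polisher chosen for its clean behaviour on
# the random-vs-systematic error distinction: independent read errors are
# outvoted at adequate depth, while an error shared by more than half the
# reads at a locus survives into the consensus.

#' Consensus-building parameters
#'
#' @param polish_rounds maximum majority-vote polishing rounds per assembly
#'   (stops early when a round leaves the draft unchanged).
#' @param iterations number of shuffled/rotated assemblies feeding the final
#'   meta-assembly.
#' @param seed integer seed driving read shuffling (all randomness in the
#'   consensus stage flows from it).
#' @param tie_rule `"prefer_current"` keeps the current draft symbol on vote
#'   ties (keeps polishing a contraction); `"lexicographic"` picks the
#'   alphabetically first symbol.
#' @param min_depth positions covered by fewer reads keep the draft base.
#' @param circular treat the reference as circular (single bacterial-style
#'   chromosome); rotation is only meaningful for circular references.
#' @return a `consensus_params` object.
#' @export
consensus_params <- function(polish_rounds = 4L, iterations = 10L, seed = 1L,
                             tie_rule = c("prefer_current", "lexicographic"),
                             min_depth = 1L, circular = TRUE) {
  if (polish_rounds < 1) abort("polish_rounds must be >= 1")
  if (iterations < 1) abort("iterations must be >= 1")
  if (min_depth < 1) abort("min_depth must be >= 1")
  structure(list(polish_rounds = as.integer(polish_rounds),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 tie_rule = match.arg(tie_rule),
                 min_depth = as.integer(min_depth),
                 circular = isTRUE(circular)),
            class = "consensus_params")
}

#' Rotate a sequence to a new start position
#'
#' @param seq sequence string.
#' @param offset new start, `0 <= offset < nchar(seq)`.
#' @return `seq[offset:] + seq[:offset]` (0-based slicing).
#' @export
rotate_sequence <- function(seq, offset) {
  n <- nchar(seq)
  if (offset < 0 || offset >= max(n, 1)) abort("offset out of range")
  if (offset == 0) return(seq)
  paste0(substring(seq, offset + 1, n), substring(seq, 1, offset))
}

# oriented view of reads used by tiling and pileup: sequence on the
# alignment strand plus query offsets in that orientation
oriented_reads <- function(alignments, reads) {
  seqs <- reads$seq[match(alignments$read_id, reads$id)]
  minus <- !is.na(alignments$strand) & alignments$strand == "-"
  seqs[minus] <- reverse_complement(seqs[minus])
  q0 <- ifelse(minus, alignments$read_len - alignments$query_end,
               alignments$query_start)
  q1 <- ifelse(minus, alignments$read_len - alignments$query_start,
               alignments$query_end)
  list(seq = seqs, q0 = q0, q1 = q1)
}

#' Tile a reference with read sequence
#'
#' Greedily covers the reference with the highest-identity alignments and
#' substitutes each covered span with the read's aligned subsequence;
#' uncovered spans keep the reference sequence. With no reads the draft is
#' the reference itself. This is the replacement step of reference-guided
#' assembly: the draft inherits the reference's large-scale structure but
#' its small-scale sequence comes from the reads.
#'
#' @param reference the reference (string or one-row sequence tibble).
#' @param alignments alignment tibble of the reads against that reference.
#' @param reads sequence tibble of reads.
#' @param circular treat the reference as circular.
#' @return the draft sequence string.
#' @export
tile_reference <- function(reference, alignments, reads, circular = TRUE) {
  ref <- as_one_seq(reference)
  L <- nchar(ref$seq)
  aln <- alignments[alignments$aligned %in% TRUE, , drop = FALSE]
  if (!nrow(aln)) return(ref$seq)
  ord <- order(-aln$identity, aln$read_id)
  aln <- aln[ord, , drop = FALSE]
  ori <- oriented_reads(aln, reads)

  owner <- integer(L)  # 0 = reference
  for (a in seq_len(nrow(aln))) {
    span <- seq.int(aln$ref_start[[a]], aln$ref_end[[a]] - 1L)
    idx <- if (circular) (span %% L) + 1L else span[span < L] + 1L
    free <- owner[idx] == 0L
    owner[idx[free]] <- a
  }

  runs <- rle(owner)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths  # 0-based starts
  pieces <- character(length(runs$values))
  for (r in seq_along(runs$values)) {
    a <- runs$values[[r]]
    s <- starts[[r]]; e <- ends[[r]]
    if (a == 0L) {
      pieces[[r]] <- substring(ref$seq, s + 1L, e)
    } else {
      # lift the wrapped run into the alignment's own coordinate frame
      rs <- aln$ref_start[[a]]; re <- aln$ref_end[[a]]
      if (s < rs) { s <- s + L; e <- e + L }
      s <- max(s, rs); e <- min(e, re)
      if (e <= s) { pieces[[r]] <- ""; next }
      qi <- cpp_query_interval(aln$cigar[[a]], rs, ori$q0[[a]], s, e)
      pieces[[r]] <- substring(ori$seq[[a]], qi[[1]] + 1L, qi[[2]])
    }
  }
  paste0(pieces, collapse = "")
}

#' One majority-vote polishing round
#'
#' Realigns all reads to the draft, builds a pileup, and emits at every
#' draft position the plurality symbol: a base, a deletion, or a base plus
#' an insertion. An insertion is emitted only when its most common inserted
#' string is carried by at least half of the reads covering the junction.
#' Positions covered by fewer than `min_depth` reads keep the draft base.
#'
#' @param draft draft sequence string.
#' @param reads sequence tibble of reads.
#' @param params a [consensus_params()].
#' @param scoring a [scoring_scheme()].
#' @param k seed k-mer size for the realignment.
#' @return the polished sequence string.
#' @export
polish_round <- function(draft, reads, params = consensus_params(),
                         scoring = scoring_scheme(), k = 15) {
  if (!nzchar(draft)) abort("draft must be non-empty")
  idx <- ref_index(draft, k = k, circular = params$circular)
  aln <- align_reads(reads, idx, scoring)
  aln <- aln[aln$aligned %in% TRUE, , drop = FALSE]
  if (!nrow(aln)) return(draft)
  ori <- oriented_reads(aln, reads)
  cpp_pileup_polish(draft, nchar(draft), params$circular,
                    as.integer(aln$ref_start), as.integer(ori$q0),
                    aln$cigar, ori$seq, params$min_depth,
                    params$tie_rule == "prefer_current")
}

#' Single reference-guided assembly (replace, then polish)
#'
#' Tiles the reference with read sequence, then applies up to
#' `params$polish_rounds` majority-vote polishing rounds, stopping early
#' when a round leaves the draft unchanged.
#'
#' @inheritParams polish_round
#' @param reference the reference (string or one-row sequence tibble).
#' @return a one-row sequence tibble holding the assembly.
#' @export
rebaler_lite <- function(reference, reads, params = consensus_params(),
                         scoring = scoring_scheme(), k = 15) {
  ref <- as_one_seq(reference)
  idx <- ref_index(ref$seq, k = k, circular = params$circular)
  aln <- align_reads(reads, idx, scoring)
  draft <- tile_reference(ref$seq, aln, reads, circular = params$circular)
  for (round in seq_len(params$polish_rounds)) {
    polished <- polish_round(draft, reads, params, scoring, k)
    if (identical(polished, draft)) break
    draft <- polished
  }
  seq_tbl(paste0(ref$id, "_consensus"), draft)
}

# restore the canonical start of a circular assembly by locating a unique
# anchor taken from the original reference start
canonical_start <- function(assembly, reference_seq, scoring, k = 15) {
  anchor_len <- min(1000L, nchar(reference_seq))
  anchor <- substring(reference_seq, 1L, anchor_len)
  idx <- ref_index(assembly, k = k, circular = TRUE)
  aln <- align_reads(seq_tbl("anchor", anchor), idx, scoring)
  if (!isTRUE(aln$aligned[[1]]) || aln$strand[[1]] != "+") {
    warn("could not locate the reference start anchor; assembly left unrotated")
    return(assembly)
  }
  rotate_sequence(assembly, aln$ref_start[[1]] %% nchar(assembly))
}

#' Iterative consensus with shuffled reads and rotated starts
#'
#' Runs `params$iterations` independent assemblies, each with the reads
#' shuffled under a seeded RNG and (for circular references) the reference
#' rotated by `floor(i * L / iterations)`; each result is rotated back to
#' the canonical start and the set of per-iteration assemblies is fed as the
#' 'reads' of a final assembly against the original reference. The
#' per-iteration assemblies differ slightly where polishing has not
#' converged to the best sequence, and the final majority vote across them
#' removes a share of those residual errors.
#'
#' @inheritParams rebaler_lite
#' @return a one-row sequence tibble holding the final assembly.
#' @export
iterative_consensus <- function(reference, reads, params = consensus_params(),
                                scoring = scoring_scheme(), k = 15) {
  ref <- as_one_seq(reference)
  L <- nchar(ref$seq)
  assemblies <- character(params$iterations)
  for (i in seq_len(params$iterations)) {
    ord <- with_seed(params$seed + i, sample.int(nrow(reads)))
    offset <- floor((i - 1) * L / params$iterations)
    ref_i <- if (params$circular && offset > 0) {
      rotate_sequence(ref$seq, offset)
    } else ref$seq
    asm <- rebaler_lite(ref_i, reads[ord, , drop = FALSE], params, scoring, k)
    s <- asm$seq[[1]]
    if (params$circular && offset > 0) {
      s <- canonical_start(s, ref$seq, scoring, k)
    }
    assemblies[[i]] <- s
  }
  meta_reads <- seq_tbl(sprintf("iter_%02d", seq_len(params$iterations)),
                        assemblies)
  out <- rebaler_lite(ref$seq, meta_reads, params, scoring, k)
  seq_tbl(paste0(ref$id, "_consensus"), out$seq[[1]])
}
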