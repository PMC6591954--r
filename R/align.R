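# Seeded, banded pairwise alignment of reads (and consensus chunks) to a
# reference. All identity and error computations downstream run off the
# operation-level alignments produced here.
#
# Conventions: coordinates are 0-based, half-open, forward strand of the
# reference; minus-strand reads are reverse-complemented before alignment and
# `query_start`/`query_end` are reported in original read coordinates.
# Circular references are handled by indexing the doubled sequence and
# re-mapping coordinates modulo the length.

#' Alignment scoring scheme
#'
#' Affine-gap scoring with positive penalties: a gap of length g costs
#' `gap_open + g * gap_extend`. Defaults are ONT-style (match 2, mismatch 4,
#' gap open 4, gap extend 2).
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (> 0).
#' @param gap_open,gap_extend affine gap penalties (> 0).
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2, mismatch = 4, gap_open = 4, gap_extend = 2) {
  if (match <= 0 || mismatch <= 0 || gap_open <= 0 || gap_extend <= 0) {
    abort("scoring_scheme: match reward and penalties must be positive")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Index a reference for seeded alignment
#'
#' Builds a k-mer position index once per run. For circular references the
#' doubled sequence is indexed so reads spanning the origin still seed and
#' align contiguously; reported coordinates are re-mapped so that
#' `ref_start < length`.
#'
#' @param reference a single reference sequence (string or one-row sequence
#'   tibble).
#' @param k seed k-mer size (>= 11).
#' @param circular treat the reference as circular.
#' @return a `ref_index` object.
#' @export
ref_index <- function(reference, k = 15, circular = FALSE) {
  if (k < 11) abort("seed k-mer size must be >= 11")
  r <- as_one_seq(reference)
  if (!nzchar(r$seq)) abort("reference sequence is empty")
  indexed <- if (circular) paste0(r$seq, r$seq) else r$seq
  structure(list(id = r$id, seq = r$seq, indexed_seq = indexed,
                 len = nchar(r$seq), k = as.integer(k), circular = circular,
                 ptr = cpp_index_kmers(indexed, as.integer(k))),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> %s: %s bp, k = %d, %s\n", x$id,
              format(x$len, big.mark = ","), x$k,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

empty_alignment_row <- function(read_id, ref_id, read_len) {
  tibble(read_id = read_id, ref_id = ref_id, strand = NA_character_,
         ref_start = NA_integer_, ref_end = NA_integer_,
         query_start = NA_integer_, query_end = NA_integer_,
         read_len = read_len, score = NA_integer_, cigar = NA_character_,
         nmatch = NA_real_, nmismatch = NA_real_, nins = NA_real_,
         ndel = NA_real_, identity = NA_real_, aligned_fraction = 0,
         aligned = FALSE)
}

# banded alignment centred on a diagonal, widening the band (doubling) when
# the optimal path touches the band edge
align_centred <- function(query, target, scoring, diag_centre, band, max_band) {
  repeat {
    res <- cpp_align_banded(query, target, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            as.integer(diag_centre - band),
                            as.integer(diag_centre + band))
    if (isTRUE(res$ok) && !isTRUE(res$band_hit)) return(res)
    if (band >= max_band) return(res)
    band <- min(max_band, band * 2L)
  }
}

#' Seed a read against an indexed reference
#'
#' Finds the reference window and strand maximising the count of collinear
#' exact k-mer matches within a diagonal band. Returns `NULL` when the best
#' collinear seed count falls below `min_seeds` (the read is recorded as
#' unaligned) or when the read is shorter than k.
#'
#' @param read a read sequence string.
#' @param index a [ref_index()].
#' @param min_seeds minimum collinear k-mer count to accept a candidate.
#' @param margin window padding as a fraction of read length.
#' @param max_hits k-mers with more reference positions than this are
#'   skipped as repeats.
#' @return `NULL`, or a list with `strand`, `window_start`, `window_end`
#'   (in indexed-sequence coordinates) and `diag_centre` (window-relative).
#' @export
seed_anchor <- function(read, index, min_seeds = 3, margin = 0.15,
                        max_hits = 100L) {
  len <- nchar(read)
  if (len < index$k) return(NULL)
  bucket <- 50L  # diagonal bucket width; adjacent buckets merge, so indel
                 # drift up to ~2 buckets still counts as collinear
  fwd <- cpp_seed_hits(index$ptr, read, bucket, max_hits)
  rev <- cpp_seed_hits(index$ptr, reverse_complement(read), bucket, max_hits)
  if (max(fwd$count, rev$count) < min_seeds) return(NULL)
  strand <- if (fwd$count >= rev$count) "+" else "-"
  hit <- if (strand == "+") fwd else rev
  pad <- ceiling(margin * len)
  ilen <- nchar(index$indexed_seq)
  wstart <- max(0, hit$diag_lo - pad)
  wend <- min(ilen, hit$diag_hi + len + pad)
  list(strand = strand, window_start = as.integer(wstart),
       window_end = as.integer(wend),
       diag_centre = as.integer((hit$diag_lo + hit$diag_hi) / 2 - wstart),
       seed_count = hit$count)
}

#' Align reads to an indexed reference
#'
#' One best alignment per read (no split or supplementary alignments);
#' reads that fail seeding or banded alignment appear as unaligned rows with
#' `aligned = FALSE`.
#'
#' @param reads a sequence tibble of reads.
#' @param index a [ref_index()].
#' @param scoring a [scoring_scheme()].
#' @param band initial band half-width; default scales with read length.
#' @param max_band band-widening limit before a read is recorded unaligned.
#' @inheritParams seed_anchor
#' @return an alignment tibble, one row per read, in input order. Columns
#'   include 0-based half-open `ref_start`/`ref_end` and
#'   `query_start`/`query_end` (original read coordinates), the extended
#'   cigar (`=`/`X`/`I`/`D`), operation-length counts, BLAST `identity` and
#'   `aligned_fraction`.
#' @export
align_reads <- function(reads, index, scoring = scoring_scheme(),
                        band = NULL, max_band = 4096L, min_seeds = 3,
                        margin = 0.15, max_hits = 100L) {
  if (!nrow(reads)) return(empty_alignment_row(character(), character(), integer()))
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rows[[i]] <- align_one(reads$id[[i]], reads$seq[[i]], index, scoring,
                           band, max_band, min_seeds, margin, max_hits)
  }
  dplyr::bind_rows(rows)
}

align_one <- function(read_id, seq, index, scoring, band, max_band,
                      min_seeds, margin, max_hits) {
  len <- nchar(seq)
  anchor <- seed_anchor(seq, index, min_seeds, margin, max_hits)
  if (is.null(anchor)) return(empty_alignment_row(read_id, index$id, len))
  oriented <- if (anchor$strand == "+") seq else reverse_complement(seq)
  target <- substring(index$indexed_seq, anchor$window_start + 1L,
                      anchor$window_end)
  if (is.null(band)) band <- 128L  # covers seed-bucket slack plus indel
                                   # drift; doubled on demand up to max_band
  res <- align_centred(oriented, target, scoring, anchor$diag_centre,
                       as.integer(band), as.integer(max_band))
  if (!isTRUE(res$ok)) return(empty_alignment_row(read_id, index$id, len))

  t0 <- anchor$window_start + res$t0
  t1 <- anchor$window_start + res$t1
  if (index$circular && t0 >= index$len) {
    t0 <- t0 - index$len
    t1 <- t1 - index$len
  }
  # query interval in original read coordinates
  if (anchor$strand == "+") {
    q0 <- res$q0; q1 <- res$q1
  } else {
    q0 <- len - res$q1; q1 <- len - res$q0
  }
  ncol_total <- res$nmatch + res$nmismatch + res$nins + res$ndel
  tibble(read_id = read_id, ref_id = index$id, strand = anchor$strand,
         ref_start = as.integer(t0), ref_end = as.integer(t1),
         query_start = as.integer(q0), query_end = as.integer(q1),
         read_len = len, score = res$score, cigar = res$cigar,
         nmatch = res$nmatch, nmismatch = res$nmismatch,
         nins = res$nins, ndel = res$ndel,
         identity = res$nmatch / ncol_total,
         aligned_fraction = (res$q1 - res$q0) / len,
         aligned = TRUE)
}

#' Banded pairwise alignment of two sequences
#'
#' Semi-global alignment: the query is aligned end to end while target
#' end-gaps are free. The dynamic programme is restricted to diagonals
#' within `band` of the corridor between the matrix corners and the band is
#' doubled (up to `max_band`) whenever the optimal path touches its edge,
#' so with a sufficient band the result equals unbanded affine-gap DP.
#'
#' @param query,target sequence strings.
#' @param scoring a [scoring_scheme()].
#' @param band band half-width around the corner-to-corner corridor.
#' @param max_band widening limit.
#' @return a one-row alignment tibble (see [align_reads()]), or an
#'   unaligned row if no path exists within `max_band`.
#' @export
align_banded <- function(query, target, scoring = scoring_scheme(),
                         band = 32L, max_band = 4096L) {
  query <- check_sequence(query, "query")
  target <- check_sequence(target, "target")
  if (!nzchar(query) || !nzchar(target)) abort("query and target must be non-empty")
  if (band < 1) abort("band must be >= 1")
  m <- nchar(query); n <- nchar(target)
  # corridor [0, n - m] always inside the band so corners stay connected
  repeat {
    res <- cpp_align_banded(query, target, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            as.integer(min(0L, n - m) - band),
                            as.integer(max(0L, n - m) + band))
    if (isTRUE(res$ok) && !isTRUE(res$band_hit)) break
    if (band >= max_band) break
    band <- min(max_band, band * 2L)
  }
  if (!isTRUE(res$ok)) return(empty_alignment_row("query", "target", m))
  ncol_total <- res$nmatch + res$nmismatch + res$nins + res$ndel
  tibble(read_id = "query", ref_id = "target", strand = "+",
         ref_start = res$t0, ref_end = res$t1,
         query_start = res$q0, query_end = res$q1,
         read_len = m, score = res$score, cigar = res$cigar,
         nmatch = res$nmatch, nmismatch = res$nmismatch,
         nins = res$nins, ndel = res$ndel,
         identity = res$nmatch / ncol_total,
         aligned_fraction = (res$q1 - res$q0) / m,
         aligned = TRUE)
}

#' BLAST identity of alignments
#'
#' Matching bases divided by total alignment length, counting every column:
#' matches, mismatches, inserted and deleted bases.
#'
#' @param aln an alignment tibble (rows from [align_reads()] or
#'   [align_banded()]), or a character vector of extended cigars.
#' @return numeric identity per alignment; `NA` for unaligned rows.
#' @export
blast_identity <- function(aln) {
  if (is.character(aln)) {
    return(vapply(aln, function(cig) {
      ops <- cpp_cigar_ops(cig)
      tot <- sum(ops$len)
      if (tot == 0) abort("alignment has no operations")
      sum(ops$len[ops$op == "="]) / tot
    }, numeric(1), USE.NAMES = FALSE))
  }
  tot <- aln$nmatch + aln$nmismatch + aln$nins + aln$ndel
  if (any(!is.na(tot) & tot == 0)) abort("alignment has no operations")
  aln$nmatch / tot
}

#' Aligned fraction of a read
#'
#' Fraction of the read covered by its alignment's query interval; 0 for
#' unaligned reads.
#'
#' @param aln an alignment tibble.
#' @param read_length read lengths; defaults to the tibble's `read_len`.
#' @return numeric vector in \[0, 1\].
#' @export
aligned_fraction <- function(aln, read_length = aln$read_len) {
  if (any(read_length < 1, na.rm = TRUE)) abort("read_length must be >= 1")
  out <- (aln$query_end - aln$query_start) / read_length
  out[is.na(out) | !aln$aligned] <- 0
  out
}

#' Expand an extended cigar into an operation tibble
#'
#' @param cigar a single extended-cigar string (`=`, `X`, `I`, `D`).
#' @return a tibble with columns `op` and `len`.
#' @export
cigar_ops <- function(cigar) {
  as_tibble(cpp_cigar_ops(cigar))
}

#' Export alignments as a tab-separated table
#'
#' @param aln an alignment tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  write.table(aln, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
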