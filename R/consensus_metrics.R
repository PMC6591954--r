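# Chunked consensus accuracy and the consensus-error taxonomy: differences
# between an assembly and the reference are extracted from alignments and
# classified by reference context as Dcm-motif errors, homopolymer
# insertions/deletions, or plain insertions/deletions/substitutions.
#
# Classification precedence is Dcm > homopolymer > plain, so the categories
# partition the events: an error inside a CCAGG/CCTGG motif that also
# changes a homopolymer length counts as Dcm.

ERROR_CLASSES <- c("dcm", "homopolymer_insertion", "homopolymer_deletion",
                   "insertion", "deletion", "substitution")

#' Split an assembly into evaluation chunks
#'
#' Consecutive non-overlapping pieces of `chunk_bp` (default 10 kbp); a
#' trailing piece shorter than half a chunk is merged into the previous
#' piece, otherwise kept. An assembly shorter than one chunk yields a
#' single chunk.
#'
#' @param assembly assembly sequence (string or one-row sequence tibble).
#' @param chunk_bp chunk size in bp (>= 1000).
#' @return a tibble with columns `id`, `start` (0-based offset in the
#'   assembly), `length`, `seq`.
#' @export
chunk_assembly <- function(assembly, chunk_bp = 10000L) {
  if (chunk_bp < 1000) abort("chunk_bp must be >= 1000")
  a <- as_one_seq(assembly, "assembly")
  L <- nchar(a$seq)
  if (L <= chunk_bp) {
    return(tibble(id = "chunk_001", start = 0L, length = L, seq = a$seq))
  }
  n_full <- L %/% chunk_bp
  rem <- L - n_full * chunk_bp
  starts <- (seq_len(n_full) - 1L) * chunk_bp
  ends <- starts + chunk_bp
  if (rem >= chunk_bp / 2) {
    starts <- c(starts, n_full * chunk_bp)
    ends <- c(ends, L)
  } else {
    ends[[length(ends)]] <- L
  }
  tibble(id = sprintf("chunk_%03d", seq_along(starts)),
         start = as.integer(starts),
         length = as.integer(ends - starts),
         seq = substring(a$seq, starts + 1L, ends))
}

#' Align and score assembly chunks against the reference
#'
#' Each chunk is located and aligned with the same seeded banded aligner
#' used for reads; a chunk that fails to align scores identity 0 (with a
#' warning).
#'
#' @param chunks tibble from [chunk_assembly()].
#' @param index a [ref_index()] of the reference.
#' @param scoring a [scoring_scheme()].
#' @return the chunk tibble with an added `identity` column, plus the
#'   alignment tibble as attribute `"alignments"`.
#' @export
score_chunks <- function(chunks, index, scoring = scoring_scheme()) {
  aln <- align_reads(seq_tbl(chunks$id, chunks$seq), index, scoring)
  ident <- blast_identity(aln)
  failed <- !(aln$aligned %in% TRUE)
  if (any(failed)) {
    warn(sprintf("%d chunk(s) failed to align; scored as identity 0",
                 sum(failed)))
    ident[failed] <- 0
  }
  out <- chunks
  out$identity <- ident
  attr(out, "alignments") <- aln
  out
}

#' Consensus accuracy over assembly chunks
#'
#' Overall consensus accuracy is the median BLAST identity of the chunks,
#' reported with its qscore and the sample standard deviation across
#' chunks.
#'
#' @param chunks tibble from [chunk_assembly()].
#' @param index a [ref_index()] of the reference.
#' @param scoring a [scoring_scheme()].
#' @param q_cap qscore reported for a perfect consensus.
#' @return a one-row tibble: `median_chunk_identity`, `consensus_qscore`,
#'   `chunk_identity_sd`, `n_chunks`; the scored chunk tibble is attached
#'   as attribute `"chunks"`.
#' @export
consensus_identity <- function(chunks, index, scoring = scoring_scheme(),
                               q_cap = 90) {
  if (!nrow(chunks)) abort("need at least one chunk")
  scored <- score_chunks(chunks, index, scoring)
  out <- tibble(
    median_chunk_identity = median(scored$identity),
    consensus_qscore = identity_to_qscore(median(scored$identity), q_cap),
    chunk_identity_sd = if (nrow(scored) > 1) sd(scored$identity) else 0,
    n_chunks = nrow(scored)
  )
  attr(out, "chunks") <- scored
  out
}

#' Locate Dcm motif sites on a reference
#'
#' Forward-strand occurrences of the motifs (default CCAGG/CCTGG, the Dcm
#' methylation pair). The pair is closed under reverse complement, so a
#' forward scan covers both strands by construction. Overlapping intervals
#' are unioned for membership queries.
#'
#' @param reference reference sequence (string or one-row sequence tibble).
#' @param motifs motif strings.
#' @return a tibble with 0-based half-open `start`, `end` and `motif`
#'   columns; the unioned [IRanges::IRanges] is attached as attribute
#'   `"ranges"`.
#' @export
find_motif_sites <- function(reference, motifs = c("CCAGG", "CCTGG")) {
  if (!length(motifs)) abort("motifs must be non-empty")
  ref <- as_one_seq(reference)
  subject <- Biostrings::DNAString(ref$seq)
  hits <- lapply(motifs, function(m) {
    v <- Biostrings::matchPattern(m, subject)
    tibble(start = BiocGenerics::start(v) - 1L,
           end = BiocGenerics::end(v),
           motif = rep(m, length(v)))
  })
  out <- dplyr::arrange(dplyr::bind_rows(hits), .data$start)
  rng <- IRanges::reduce(IRanges::IRanges(start = out$start + 1L, end = out$end))
  attr(out, "ranges") <- rng
  out
}

#' Find homopolymer runs on a reference
#'
#' Maximal runs of identical bases of at least `min_len` (default 3, the
#' conventional threshold below which nanopore length errors are not
#' considered homopolymer-driven).
#'
#' @inheritParams find_motif_sites
#' @param min_len minimum run length (>= 2).
#' @return a tibble with 0-based `start`, `length` and `base` columns.
#' @export
find_homopolymers <- function(reference, min_len = 3L) {
  if (min_len < 2) abort("min_len must be >= 2")
  ref <- as_one_seq(reference)
  r <- rle(strsplit(ref$seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  tibble(start = as.integer(ends - r$lengths)[keep],
         length = as.integer(r$lengths)[keep],
         base = r$values[keep])
}

#' Extract error events from an alignment
#'
#' Each mismatch column becomes one substitution event (multi-base mismatch
#' runs are split per base); each gap run becomes a single insertion or
#' deletion event carrying the full run as its allele. Coordinates are
#' lifted to global reference space (`chunk_offset` plus, for circular
#' references, wrapping modulo the reference length).
#'
#' @param aln a one-row alignment tibble (query = assembly chunk).
#' @param reference reference sequence (string or one-row tibble).
#' @param query the aligned query sequence, oriented to the alignment
#'   strand.
#' @param chunk_offset offset added to reference positions.
#' @param wrap_len if positive, reference positions are wrapped modulo this
#'   length (circular references aligned through the doubled sequence).
#' @return a tibble of events: `ref_pos` (0-based; for insertions the
#'   position immediately right of the junction), `kind`, `ref_allele`,
#'   `alt_allele`.
#' @export
extract_errors <- function(aln, reference, query, chunk_offset = 0L,
                           wrap_len = 0L) {
  if (!isTRUE(aln$aligned[[1]])) {
    return(tibble(ref_pos = integer(), kind = character(),
                  ref_allele = character(), alt_allele = character()))
  }
  ref <- as_one_seq(reference)
  ops <- cigar_ops(aln$cigar[[1]])
  t <- aln$ref_start[[1]]
  # cigar coordinates refer to the strand-oriented query
  q <- if (identical(aln$strand[[1]], "-")) {
    aln$read_len[[1]] - aln$query_end[[1]]
  } else {
    aln$query_start[[1]]
  }
  events <- vector("list", nrow(ops))
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[[i]]; len <- ops$len[[i]]
    if (op == "X") {
      pos <- t + seq_len(len) - 1L
      events[[i]] <- tibble(
        ref_pos = pos,
        kind = "substitution",
        ref_allele = vapply(pos, function(p) {
          pp <- if (wrap_len > 0) p %% wrap_len else p
          substring(ref$seq, pp + 1L, pp + 1L)
        }, character(1)),
        alt_allele = strsplit(substring(query, q + 1L, q + len), "")[[1]]
      )
      t <- t + len; q <- q + len
    } else if (op == "I") {
      events[[i]] <- tibble(ref_pos = t, kind = "insertion",
                            ref_allele = "",
                            alt_allele = substring(query, q + 1L, q + len))
      q <- q + len
    } else if (op == "D") {
      ref_allele <- paste0(vapply(t + seq_len(len) - 1L, function(p) {
        pp <- if (wrap_len > 0) p %% wrap_len else p
        substring(ref$seq, pp + 1L, pp + 1L)
      }, character(1)), collapse = "")
      events[[i]] <- tibble(ref_pos = t, kind = "deletion",
                            ref_allele = ref_allele, alt_allele = "")
      t <- t + len
    } else {
      t <- t + len; q <- q + len
    }
  }
  out <- dplyr::bind_rows(events)
  if (nrow(out)) {
    out$ref_pos <- out$ref_pos + as.integer(chunk_offset)
    if (wrap_len > 0) out$ref_pos <- out$ref_pos %% as.integer(wrap_len)
  }
  out
}

all_same_base <- function(s) {
  nzchar(s) & vapply(strsplit(s, ""), function(ch) length(unique(ch)) == 1L,
                     logical(1))
}

#' Classify error events by reference context
#'
#' Precedence Dcm > homopolymer > plain. An event is Dcm when its
#' reference footprint touches a motif interval (for a deletion, any
#' deleted base; for an insertion, the junction's right neighbour). A
#' non-Dcm indel is a homopolymer insertion/deletion when it adds or
#' removes copies of base b adjacent to (or within) a reference run of b of
#' qualifying length. Everything else keeps its plain kind.
#'
#' @param events tibble from [extract_errors()].
#' @param motif_sites tibble from [find_motif_sites()].
#' @param homopolymers tibble from [find_homopolymers()].
#' @return `events` with a `klass` column added.
#' @export
classify_errors <- function(events, motif_sites, homopolymers) {
  if (!nrow(events)) {
    events$klass <- character()
    return(events)
  }
  rng <- attr(motif_sites, "ranges")
  if (is.null(rng)) {
    rng <- IRanges::reduce(IRanges::IRanges(start = motif_sites$start + 1L,
                                            end = motif_sites$end))
  }
  foot_start <- events$ref_pos + 1L
  foot_end <- ifelse(events$kind == "deletion",
                     events$ref_pos + pmax(nchar(events$ref_allele), 1L),
                     events$ref_pos + 1L)
  ev_rng <- IRanges::IRanges(start = foot_start, end = foot_end)
  in_motif <- IRanges::overlapsAny(ev_rng, rng)

  klass <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (in_motif[[i]]) {
      klass[[i]] <- "dcm"
      next
    }
    kind <- events$kind[[i]]
    p <- events$ref_pos[[i]]
    if (kind == "insertion" && all_same_base(events$alt_allele[[i]])) {
      b <- substring(events$alt_allele[[i]], 1L, 1L)
      hp <- homopolymers[homopolymers$base == b, , drop = FALSE]
      # junction between p-1 and p is adjacent to run [s, s+l) when
      # s <= p <= s+l (both flanks included)
      if (any(hp$start <= p & p <= hp$start + hp$length)) {
        klass[[i]] <- "homopolymer_insertion"
        next
      }
    }
    if (kind == "deletion" && all_same_base(events$ref_allele[[i]])) {
      b <- substring(events$ref_allele[[i]], 1L, 1L)
      len <- nchar(events$ref_allele[[i]])
      hp <- homopolymers[homopolymers$base == b, , drop = FALSE]
      if (any(hp$start <= p & p + len <= hp$start + hp$length)) {
        klass[[i]] <- "homopolymer_deletion"
        next
      }
    }
    klass[[i]] <- kind
  }
  events$klass <- klass
  events
}

#' Tally an error profile
#'
#' Counts, error bases, and per-100-bp rates per class. Both event counts
#' (a multi-base gap is one event) and base tallies (allele lengths) are
#' reported, since conventions differ on whether a multi-base homopolymer
#' length change is one error or several.
#'
#' @param events classified events from [classify_errors()].
#' @param reference_length reference length in bp.
#' @return an `error_profile` object; `tidy()` returns the per-class table,
#'   `glance()` the totals.
#' @export
error_profile <- function(events, reference_length) {
  if (reference_length < 1) abort("reference_length must be >= 1")
  if (nrow(events) && is.null(events$klass)) {
    abort("events must be classified first (see classify_errors())")
  }
  bases <- if (nrow(events)) {
    pmax(nchar(events$ref_allele), nchar(events$alt_allele), 1L)
  } else integer()
  tab <- tibble(klass = factor(if (nrow(events)) events$klass else character(),
                               levels = ERROR_CLASSES),
                bases = bases)
  tab <- dplyr::summarise(dplyr::group_by(tab, .data$klass, .drop = FALSE),
                          count = dplyr::n(), bases = sum(.data$bases))
  tab$rate_per_100bp <- 100 * tab$count / reference_length
  tab$base_rate_per_100bp <- 100 * tab$bases / reference_length
  tab$klass <- as.character(tab$klass)
  structure(list(table = tab,
                 total_errors = sum(tab$count),
                 total_error_bases = sum(tab$bases),
                 total_error_pct = 100 * sum(tab$bases) / reference_length,
                 reference_length = as.integer(reference_length)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %d errors (%.4f%% of %s bp)\n",
              x$total_errors, x$total_error_pct,
              format(x$reference_length, big.mark = ",")))
  print(x$table)
  invisible(x)
}

#' @rdname error_profile
#' @param x an `error_profile`.
#' @param ... unused.
#' @method tidy error_profile
#' @export
tidy.error_profile <- function(x, ...) x$table

#' @rdname error_profile
#' @method glance error_profile
#' @export
glance.error_profile <- function(x, ...) {
  tibble(total_errors = x$total_errors,
         total_error_bases = x$total_error_bases,
         total_error_pct = x$total_error_pct,
         reference_length = x$reference_length)
}

#' Export error events as a BED-like TSV
#'
#' @param events classified events tibble.
#' @param ref_id reference name for the first column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_errors <- function(events, ref_id, path) {
  bed <- tibble(ref = ref_id, start = events$ref_pos,
                end = events$ref_pos + pmax(nchar(events$ref_allele), 1L),
                kind = events$kind, klass = events$klass,
                ref_allele = events$ref_allele,
                alt_allele = events$alt_allele)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
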