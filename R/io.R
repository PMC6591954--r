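# FASTA/FASTQ reading and writing, qscore conversions, sequence utilities.
#
# Parsing is deliberately strict: lowercase is normalised to uppercase,
# characters outside A/C/G/T/N are rejected, and errors name the offending
# line so a malformed basecaller output fails loudly rather than silently
# skewing identity statistics.

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated; record order is preserved.
#' Gzip-compressed files are accepted transparently by `.gz` extension.
#'
#' @param path path to a FASTA (or FASTA.gz) file.
#' @return a sequence tibble (see [seq_tbl()]); zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  ids <- character()
  seqs <- character()
  cur <- NULL
  cur_parts <- character()
  cur_line <- 0L
  flush_record <- function() {
    if (is.null(cur)) return()
    s <- paste0(cur_parts, collapse = "")
    if (!nzchar(s)) {
      abort(sprintf("empty sequence for record '%s' (header at line %d)", cur, cur_line))
    }
    ids[[length(ids) + 1L]] <<- cur
    seqs[[length(seqs) + 1L]] <<- s
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_record()
      cur <- sub("\\s.*$", "", substring(line, 2))
      if (!nzchar(cur)) abort(sprintf("malformed FASTA header at line %d", i))
      cur_parts <- character()
      cur_line <- i
    } else {
      if (is.null(cur)) {
        abort(sprintf("FASTA parse error at line %d: sequence before any '>' header", i))
      }
      up <- toupper(line)
      if (!grepl("^[ACGTN]+$", up)) {
        abort(sprintf("invalid sequence character at line %d", i))
      }
      cur_parts[[length(cur_parts) + 1L]] <- up
    }
  }
  flush_record()
  seq_tbl(ids, seqs)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' Only the universal modern dialect is accepted: exactly four lines per
#' record, qualities encoded as Phred+33. Multi-line FASTQ is rejected.
#' Gzip-compressed files are accepted by `.gz` extension.
#'
#' @inheritParams read_fasta
#' @return a sequence tibble with decoded integer qualities.
#' @export
read_fastq <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[[length(lines)]]))) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) return(seq_tbl(character(), character()))
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ: %d lines is not a multiple of 4", length(lines)))
  }
  n <- length(lines) %/% 4L
  ids <- character(n)
  seqs <- character(n)
  quals <- vector("list", n)
  for (r in seq_len(n)) {
    i <- (r - 1L) * 4L + 1L
    hdr <- lines[[i]]
    if (!startsWith(hdr, "@")) {
      abort(sprintf("FASTQ parse error at line %d: expected '@' header", i))
    }
    sq <- toupper(trimws(lines[[i + 1L]]))
    if (!grepl("^[ACGTN]+$", sq)) {
      abort(sprintf("invalid or empty sequence at line %d", i + 1L))
    }
    if (!startsWith(lines[[i + 2L]], "+")) {
      abort(sprintf("FASTQ parse error at line %d: expected '+' separator", i + 2L))
    }
    qs <- trimws(lines[[i + 3L]])
    if (nchar(qs) != nchar(sq)) {
      abort(sprintf("sequence/quality length mismatch for record at line %d", i))
    }
    q <- utf8ToInt(qs) - 33L
    if (any(q < 0L | q > 93L)) {
      abort(sprintf("quality characters outside Phred+33 range at line %d", i + 3L))
    }
    ids[[r]] <- sub("\\s.*$", "", substring(hdr, 2))
    seqs[[r]] <- sq
    quals[[r]] <- q
  }
  seq_tbl(ids, seqs, quals)
}

#' Write sequences as FASTA
#'
#' @param x a sequence tibble.
#' @param path output path; `.gz` compresses.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[[i]]), con)
    s <- x$seq[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write sequences as FASTQ (Phred+33)
#'
#' Records without qualities get a uniform placeholder quality of
#' `default_q`.
#'
#' @inheritParams write_fasta
#' @param default_q Phred score used when a record carries no qualities.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, default_q = 20L) {
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    q <- x$qual[[i]]
    if (is.null(q)) q <- rep(default_q, nchar(x$seq[[i]]))
    writeLines(c(paste0("@", x$id[[i]]), x$seq[[i]], "+",
                 intToUtf8(as.integer(q) + 33L)), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised; the
#' empty string maps to itself. Note the Dcm motif pair is closed under this
#' operation: `reverse_complement("CCAGG") == "CCTGG"`.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  seq <- check_sequence(seq)
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Convert identity to a Phred qscore
#'
#' `q = -10 * log10(1 - identity)`, so Q10 = 90% identity, Q20 = 99%,
#' Q30 = 99.9%. Perfect identity is capped at `q_cap` to keep summaries of
#' error-free runs finite.
#'
#' @param identity numeric vector in \[0, 1\].
#' @param q_cap qscore reported for identity 1 (and an upper bound overall).
#' @return numeric vector of qscores.
#' @export
identity_to_qscore <- function(identity, q_cap = 90) {
  if (any(is.na(identity)) || any(identity < 0 | identity > 1)) {
    abort("identity must lie in [0, 1]")
  }
  if (q_cap <= 0) abort("q_cap must be positive")
  q <- ifelse(identity >= 1, q_cap, -10 * log10(1 - identity))
  pmin(q, q_cap)
}

#' Convert a Phred qscore to identity
#'
#' @param q non-negative numeric vector of qscores.
#' @return numeric identities `1 - 10^(-q/10)`.
#' @export
qscore_to_identity <- function(q) {
  if (any(is.na(q)) || any(q < 0)) abort("qscore must be non-negative")
  1 - 10^(-q / 10)
}

#' Enumerate the k-mer state space of a nanopore model
#'
#' The narrow point of an R9.4 pore reads about five consecutive
#' nucleotides, so a basecalling model must distinguish one state per
#' possible k-mer: 4^5 = 1024 for a plain four-base alphabet, growing to
#' 5^5 = 3125 when a modified base (such as 5-methylcytosine) is added.
#' States are enumerated explicitly rather than computed as a power.
#'
#' @param n_bases alphabet size (4 = ACGT; 5 adds `M` for 5-methylcytosine).
#' @param width number of nucleotides resolved by the pore (default 5).
#' @return a tibble with one row per state and a `state` column.
#' @export
pore_state_space <- function(n_bases = 4, width = 5) {
  alphabet <- c("A", "C", "G", "T", "M")
  if (n_bases < 1 || n_bases > length(alphabet)) {
    abort(sprintf("n_bases must be in [1, %d]", length(alphabet)))
  }
  grid <- do.call(expand.grid, c(rep(list(alphabet[seq_len(n_bases)]), width),
                                 stringsAsFactors = FALSE))
  tibble(state = do.call(paste0, rev(grid)))
}

#' Count nanopore k-mer states
#'
#' @inheritParams pore_state_space
#' @return integer number of distinct k-mer states.
#' @export
n_pore_states <- function(n_bases = 4, width = 5) {
  nrow(pore_state_space(n_bases, width))
}
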