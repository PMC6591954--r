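# internal helpers shared across modules

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

check_sequence <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- !grepl("^[ACGTN]*$", seq)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  }
  seq
}

#' Build a sequence table
#'
#' The package carries sequences as tibbles with one row per record: `id`,
#' `seq` (uppercase over A/C/G/T/N) and `qual`, a list-column of integer
#' Phred scores (`NULL` where absent).
#'
#' @param id character vector of record names.
#' @param seq character vector of nucleotide sequences.
#' @param qual optional list of integer Phred vectors, length-matched to
#'   `seq`, or `NULL`.
#' @return a tibble with columns `id`, `seq`, `qual`.
#' @export
seq_tbl <- function(id, seq, qual = NULL) {
  seq <- check_sequence(seq)
  if (is.null(qual)) {
    qual <- vector("list", length(seq))
  } else {
    if (length(qual) != length(seq)) abort("qual must match seq in length")
    ok <- vapply(seq_along(seq), function(i) {
      is.null(qual[[i]]) || length(qual[[i]]) == nchar(seq[[i]])
    }, logical(1))
    if (!all(ok)) abort("quality vectors must match sequence lengths")
  }
  tibble(id = as.character(id), seq = seq, qual = qual)
}

# accept a single sequence as a string, a one-row seq tibble, or a list with
# $seq; returns list(id, seq)
as_one_seq <- function(x, what = "reference") {
  if (is.character(x) && length(x) == 1 && !grepl("[\t\n]", x)) {
    return(list(id = what, seq = check_sequence(x)))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1) {
      abort(sprintf("%s must be a single sequence (got %d records)", what, nrow(x)))
    }
    return(list(id = x$id[[1]], seq = check_sequence(x$seq[[1]])))
  }
  abort(sprintf("cannot interpret %s as a single sequence", what))
}

# run code with a private RNG stream; the session RNG state is untouched
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

open_maybe_gz <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}
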