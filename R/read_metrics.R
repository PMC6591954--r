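# Read-level accuracy: selection, per-read identity with edge rules, and
# set-level summaries.
#
# Edge rules: a read aligned over less than half its length scores 0%
# identity, as does a read expected in the basecaller output but missing
# from it. Both rules guard against inflated medians from partial or
# selectively-emitted output.

#' Select reads by reference-spanning alignment length
#'
#' Keeps reads whose alignment spans at least `min_alignment_bp` of the
#' reference (`ref_end - ref_start`). Used to restrict a read set to long,
#' confidently-placed reads; the threshold is a free parameter because the
#' appropriate value scales with genome size and depth.
#'
#' @param alignments an alignment tibble from [align_reads()].
#' @param min_alignment_bp minimum reference span in bp.
#' @return character vector of retained read ids.
#' @export
select_reads <- function(alignments, min_alignment_bp) {
  if (min_alignment_bp < 0) abort("min_alignment_bp must be >= 0")
  keep <- alignments$aligned &
    (alignments$ref_end - alignments$ref_start) >= min_alignment_bp
  alignments$read_id[which(keep)]
}

#' Score reads against their alignments
#'
#' Applies the per-read identity rules: BLAST identity when at least half
#' the read aligned; 0% identity with status `under_half_aligned` when less
#' than half aligned (strict `< 0.5`); 0% with status `unaligned` when no
#' alignment was found; 0% with status `missing` for ids in `expected_ids`
#' absent from `reads`.
#'
#' @param reads sequence tibble of basecalled reads.
#' @param alignments alignment tibble for those reads.
#' @param expected_ids ids the basecaller was expected to emit; defaults to
#'   the ids present in `reads`.
#' @return a tibble with columns `read_id`, `length`, `aligned_fraction`,
#'   `identity`, `status`.
#' @export
score_reads <- function(reads, alignments, expected_ids = NULL) {
  expected_ids <- expected_ids %||% reads$id
  aln <- alignments[match(reads$id, alignments$read_id), , drop = FALSE]
  frac <- aligned_fraction(aln)
  ident <- blast_identity(aln)
  status <- dplyr::case_when(
    !aln$aligned | is.na(aln$aligned) ~ "unaligned",
    frac < 0.5 ~ "under_half_aligned",
    TRUE ~ "aligned"
  )
  present <- tibble(
    read_id = reads$id,
    length = nchar(reads$seq),
    aligned_fraction = frac,
    identity = ifelse(status == "aligned", ident, 0),
    status = status
  )
  missing_ids <- setdiff(expected_ids, reads$id)
  if (length(missing_ids)) {
    present <- dplyr::bind_rows(present, tibble(
      read_id = missing_ids, length = NA_integer_, aligned_fraction = 0,
      identity = 0, status = "missing"))
  }
  present[present$read_id %in% c(reads$id, missing_ids), , drop = FALSE]
}

#' N50 of a set of read lengths
#'
#' Largest length L such that reads of length >= L together contain at
#' least half of all bases.
#'
#' @param lengths integer read lengths (NA dropped).
#' @return the N50 in bp (0 for an empty set).
#' @export
read_n50 <- function(lengths) {
  lengths <- sort(lengths[!is.na(lengths)], decreasing = TRUE)
  if (!length(lengths)) return(0L)
  lengths[[which(cumsum(as.numeric(lengths)) >= sum(as.numeric(lengths)) / 2)[[1]]]]
}

# mean read quality by averaging per-base error probabilities, converted
# back to the Phred scale
mean_read_q <- function(qual) {
  if (is.null(qual) || !length(qual)) return(NA_real_)
  -10 * log10(mean(10^(-qual / 10)))
}

#' Summarise a scored read set
#'
#' Overall read accuracy is the median identity across all expected reads
#' (missing and under-half-aligned reads count at 0%), reported alongside
#' its qscore, the N50, total bases, and the fraction of output reads whose
#' mean Phred quality falls below the `fail_q` threshold (ONT's 'fail'
#' threshold is Q7). Mean read quality averages per-base error
#' probabilities, not raw Phred values.
#'
#' @param results a tibble from [score_reads()].
#' @param reads the sequence tibble (optional; needed for
#'   `fraction_below_fail`, which is `NA` without qualities).
#' @param fail_q 'fail' quality threshold.
#' @param q_cap qscore cap for perfect identity.
#' @return a one-row tibble: `n_reads_expected`, `n_reads_output`,
#'   `median_identity`, `read_qscore`, `n50`, `total_bases`,
#'   `fraction_below_fail`.
#' @export
summarize_read_set <- function(results, reads = NULL, fail_q = 7, q_cap = 90) {
  if (!nrow(results)) abort("cannot summarise an empty read set")
  med <- median(results$identity)
  qs <- if (!is.null(reads) && nrow(reads)) {
    vapply(reads$qual, mean_read_q, numeric(1))
  } else NA_real_
  tibble(
    n_reads_expected = nrow(results),
    n_reads_output = sum(results$status != "missing"),
    median_identity = med,
    read_qscore = identity_to_qscore(med, q_cap),
    n50 = read_n50(results$length),
    total_bases = sum(as.numeric(results$length), na.rm = TRUE),
    fraction_below_fail = if (all(is.na(qs))) NA_real_ else
      mean(qs < fail_q, na.rm = TRUE)
  )
}
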