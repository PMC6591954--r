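# Orchestration: simulate -> files, and reads + reference -> full
# evaluation report (read metrics, iterative consensus, chunked consensus
# accuracy, error profile).

#' Write a simulated data set to a directory
#'
#' Emits `reference.fasta`, `reads.fastq`, `truth.tsv` (the injected-event
#' ledger), `layout.tsv` (per-read placement) and `config.yaml`. Identical
#' configurations produce identical directories.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_reference(config)
  sim <- simulate_reads(truth, config)
  write_fasta(truth$reference, file.path(out_dir, "reference.fasta"))
  write_fastq(sim$reads, file.path(out_dir, "reads.fastq"))
  write.table(sim$ledger, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$layout, file.path(out_dir, "layout.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$homopolymer_spec <- as.data.frame(cfg$homopolymer_spec)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Evaluate a read set against a reference
#'
#' The full pipeline: align reads, apply the per-read identity rules and
#' summarise; build the iterative reference-guided consensus; measure its
#' accuracy on chunks; extract and classify consensus errors. The
#' reference must be a single contig (multi-contig input is rejected).
#'
#' @param reads a sequence tibble, or a path to a FASTQ/FASTA file.
#' @param reference a single-record sequence tibble, or a path to a FASTA
#'   file.
#' @param min_align_bp reference-span selection threshold applied before
#'   scoring (0 keeps every aligned read).
#' @param fail_q 'fail' quality threshold for the read summary.
#' @param params a [consensus_params()].
#' @param scoring a [scoring_scheme()].
#' @param chunk_bp consensus evaluation chunk size.
#' @param skip_consensus only compute read-level metrics.
#' @param expected_ids ids expected in the basecaller output (missing ones
#'   score 0% identity).
#' @param k seed k-mer size.
#' @param q_cap qscore cap for perfect identity.
#' @param out_dir if given, per-read TSV, assembly FASTA, error TSV and a
#'   JSON report are written there.
#' @return a `bc_eval` object; see [glance.bc_eval()] and [tidy.bc_eval()].
#' @export
run_evaluate <- function(reads, reference, min_align_bp = 0, fail_q = 7,
                         params = consensus_params(),
                         scoring = scoring_scheme(), chunk_bp = 10000L,
                         skip_consensus = FALSE, expected_ids = NULL,
                         k = 15, q_cap = 90, out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1) {
    reads <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) read_fastq(reads)
             else read_fasta(reads)
  }
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_fasta(reference)
  }
  if (is.data.frame(reference) && nrow(reference) != 1) {
    abort("reference must be a single contig")
  }
  ref <- as_one_seq(reference)
  index <- ref_index(ref$seq, k = k, circular = params$circular)

  message("aligning ", nrow(reads), " reads")
  aln <- align_reads(reads, index, scoring)

  if (min_align_bp > 0) {
    keep <- select_reads(aln, min_align_bp)
    reads <- reads[reads$id %in% keep, , drop = FALSE]
    aln <- aln[aln$read_id %in% keep, , drop = FALSE]
  }

  n_alignable <- sum(aln$aligned %in% TRUE)
  if (n_alignable == 0) {
    warn("no reads aligned to the reference; accuracies reported as 0")
  }

  per_read <- score_reads(reads, aln, expected_ids)
  read_summary <- summarize_read_set(per_read, reads, fail_q, q_cap)

  consensus_summary <- tibble(median_chunk_identity = NA_real_,
                              consensus_qscore = NA_real_,
                              chunk_identity_sd = NA_real_,
                              n_chunks = 0L)
  profile <- NULL
  errors <- NULL
  assembly <- NULL
  chunk_scores <- NULL

  if (!skip_consensus) {
    if (n_alignable == 0) {
      consensus_summary <- tibble(median_chunk_identity = 0,
                                  consensus_qscore = 0,
                                  chunk_identity_sd = 0, n_chunks = 0L)
      profile <- error_profile(
        classify_errors(tibble(ref_pos = integer(), kind = character(),
                               ref_allele = character(),
                               alt_allele = character()),
                        find_motif_sites(ref$seq), find_homopolymers(ref$seq)),
        nchar(ref$seq))
    } else {
      message("building iterative consensus (", params$iterations,
              " iterations)")
      assembly <- iterative_consensus(reference, reads, params, scoring, k)
      message("scoring consensus chunks")
      chunks <- chunk_assembly(assembly, chunk_bp)
      consensus_summary <- consensus_identity(chunks, index, scoring, q_cap)
      chunk_scores <- attr(consensus_summary, "chunks")
      attr(consensus_summary, "chunks") <- NULL
      errors <- profile_assembly_errors(attr(chunk_scores, "alignments"),
                                        chunk_scores, ref, index)
      profile <- error_profile(errors, nchar(ref$seq))
    }
  }

  structure(list(read_summary = read_summary,
                 consensus_summary = consensus_summary,
                 profile = profile,
                 per_read = per_read,
                 chunk_scores = chunk_scores,
                 errors = errors,
                 assembly = assembly,
                 provenance = list(
                   seed = params$seed,
                   params_hash = rlang::hash(list(params, scoring, chunk_bp,
                                                  min_align_bp, fail_q, k)),
                   version = as.character(packageVersion("ontbench")))),
            class = "bc_eval") -> result

  if (!is.null(out_dir)) write_eval(result, ref$id, out_dir)
  result
}

# classify the differences carried by chunk-vs-reference alignments
profile_assembly_errors <- function(chunk_alns, chunk_scores, ref, index) {
  sites <- find_motif_sites(ref$seq)
  runs <- find_homopolymers(ref$seq)
  wrap_len <- if (index$circular) index$len else 0L
  ev <- vector("list", nrow(chunk_alns))
  for (i in seq_len(nrow(chunk_alns))) {
    if (!isTRUE(chunk_alns$aligned[[i]])) next
    q <- chunk_scores$seq[[i]]
    if (identical(chunk_alns$strand[[i]], "-")) q <- reverse_complement(q)
    ev[[i]] <- extract_errors(chunk_alns[i, , drop = FALSE], ref$seq, q,
                              chunk_offset = 0L, wrap_len = wrap_len)
  }
  events <- dplyr::bind_rows(ev)
  if (!nrow(events)) {
    events <- tibble(ref_pos = integer(), kind = character(),
                     ref_allele = character(), alt_allele = character())
  }
  events <- dplyr::distinct(events)  # chunk-boundary overlap safety
  classify_errors(events, sites, runs)
}

#' Classify an existing assembly against a reference
#'
#' The profiling stage alone: chunk the assembly, align the chunks, and
#' classify the consensus errors. Useful when the assembly was built
#' elsewhere.
#'
#' @param assembly assembly (string, one-row tibble, or FASTA path).
#' @inheritParams run_evaluate
#' @return a `bc_eval` object without read-level results.
#' @export
run_profile <- function(assembly, reference, params = consensus_params(),
                        scoring = scoring_scheme(), chunk_bp = 10000L,
                        k = 15, q_cap = 90) {
  if (is.character(assembly) && length(assembly) == 1 &&
      file.exists(assembly)) {
    assembly <- read_fasta(assembly)
  }
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_fasta(reference)
  }
  ref <- as_one_seq(reference)
  index <- ref_index(ref$seq, k = k, circular = params$circular)
  chunks <- chunk_assembly(assembly, chunk_bp)
  consensus_summary <- consensus_identity(chunks, index, scoring, q_cap)
  chunk_scores <- attr(consensus_summary, "chunks")
  attr(consensus_summary, "chunks") <- NULL
  errors <- profile_assembly_errors(attr(chunk_scores, "alignments"),
                                    chunk_scores, ref, index)
  structure(list(read_summary = NULL,
                 consensus_summary = consensus_summary,
                 profile = error_profile(errors, nchar(ref$seq)),
                 per_read = NULL, chunk_scores = chunk_scores,
                 errors = errors,
                 assembly = as_one_seq(assembly, "assembly") |>
                   (\(a) seq_tbl(a$id, a$seq))(),
                 provenance = list(seed = params$seed,
                                   params_hash = rlang::hash(list(params,
                                                                  scoring,
                                                                  chunk_bp)),
                                   version = as.character(
                                     packageVersion("ontbench")))),
            class = "bc_eval")
}

write_eval <- function(x, ref_id, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$per_read)) {
    write.table(x$per_read, file.path(out_dir, "per_read.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$assembly)) {
    write_fasta(x$assembly, file.path(out_dir, "assembly.fasta"))
  }
  if (!is.null(x$errors)) {
    write_errors(x$errors, ref_id, file.path(out_dir, "errors.tsv"))
  }
  report <- list(read_summary = as.list(x$read_summary),
                 consensus_summary = as.list(x$consensus_summary),
                 profile = if (!is.null(x$profile)) {
                   list(table = x$profile$table,
                        total_errors = x$profile$total_errors,
                        total_error_pct = x$profile$total_error_pct)
                 },
                 provenance = x$provenance)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.bc_eval <- function(x, ...) {
  cat("<bc_eval>\n")
  if (!is.null(x$read_summary)) {
    rs <- x$read_summary
    cat(sprintf("  reads: %d/%d output; median identity %.2f%% (Q%.1f); N50 %s bp\n",
                rs$n_reads_output, rs$n_reads_expected,
                100 * rs$median_identity, rs$read_qscore,
                format(rs$n50, big.mark = ",")))
  }
  cs <- x$consensus_summary
  if (!is.null(cs) && !is.na(cs$median_chunk_identity)) {
    cat(sprintf("  consensus: median chunk identity %.4f%% (Q%.2f) over %d chunks\n",
                100 * cs$median_chunk_identity, cs$consensus_qscore,
                cs$n_chunks))
  }
  if (!is.null(x$profile)) {
    cat(sprintf("  errors: %d (%.4f%% of reference)\n",
                x$profile$total_errors, x$profile$total_error_pct))
  }
  invisible(x)
}

#' Tidy components of an evaluation
#'
#' @param x a `bc_eval` object.
#' @param type `"reads"` (per-read results), `"chunks"`, `"errors"`, or
#'   `"profile"` (per-class error table).
#' @param ... unused.
#' @return a tibble.
#' @method tidy bc_eval
#' @export
tidy.bc_eval <- function(x, type = c("reads", "chunks", "errors", "profile"),
                         ...) {
  type <- match.arg(type)
  out <- switch(type,
                reads = x$per_read,
                chunks = x$chunk_scores,
                errors = x$errors,
                profile = if (!is.null(x$profile)) x$profile$table)
  if (is.null(out)) {
    abort(sprintf("this evaluation has no '%s' component", type))
  }
  as_tibble(as.data.frame(out))
}

#' One-row summary of an evaluation
#'
#' @param x a `bc_eval` object.
#' @param ... unused.
#' @return a one-row tibble combining read- and consensus-level summaries.
#' @method glance bc_eval
#' @export
glance.bc_eval <- function(x, ...) {
  rs <- x$read_summary %||%
    tibble(n_reads_expected = NA_integer_, n_reads_output = NA_integer_,
           median_identity = NA_real_, read_qscore = NA_real_,
           n50 = NA_integer_, total_bases = NA_real_,
           fraction_below_fail = NA_real_)
  out <- dplyr::bind_cols(rs, x$consensus_summary)
  out$total_errors <- if (!is.null(x$profile)) x$profile$total_errors else NA_integer_
  out$total_error_pct <- if (!is.null(x$profile)) x$profile$total_error_pct else NA_real_
  out
}
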