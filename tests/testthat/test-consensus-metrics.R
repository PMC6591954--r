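test_that("chunking keeps a half-size tail and merges smaller ones", {
  expect_equal(chunk_assembly(random_seq(25000))$length, c(10000L, 10000L, 5000L))
  expect_equal(chunk_assembly(random_seq(20000))$length, c(10000L, 10000L))
  expect_equal(chunk_assembly(random_seq(24000))$length, c(10000L, 14000L))
  expect_equal(chunk_assembly(random_seq(9000))$length, 9000L)
  ch <- chunk_assembly(random_seq(35000))
  expect_equal(ch$start, c(0L, 10000L, 20000L, 30000L))
  expect_error(chunk_assembly(random_seq(5000), chunk_bp = 500), ">= 1000")
})

test_that("chunked consensus identity and qscore follow the definitions", {
  withr::local_seed(51)
  ref <- random_seq(30000)
  idx <- ref_index(ref, circular = FALSE)

  perfect <- consensus_identity(chunk_assembly(ref), idx)
  expect_equal(perfect$median_chunk_identity, 1)
  expect_equal(perfect$consensus_qscore, 90)  # the cap
  expect_equal(perfect$chunk_identity_sd, 0)
  expect_equal(perfect$n_chunks, 3L)

  # one substitution per 10 kbp chunk
  ch <- strsplit(ref, "")[[1]]
  for (p in c(5000, 15000, 25000)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  mutated <- paste0(ch, collapse = "")
  one_sub <- consensus_identity(chunk_assembly(mutated), idx)
  expect_equal(one_sub$median_chunk_identity, 0.9999, tolerance = 1e-6)

  # the published identity-qscore pairing
  expect_equal(round(identity_to_qscore(0.9933), 2), 21.74)
})

test_that("motif scanning finds CCAGG/CCTGG on the forward strand only", {
  sites <- find_motif_sites("AACCAGGTT")
  expect_equal(sites$start, 2L)
  expect_equal(sites$end, 7L)

  both <- find_motif_sites("CCAGGAAACCTGGAA")
  expect_equal(both$motif, c("CCAGG", "CCTGG"))
  expect_equal(both$start, c(0L, 8L))

  expect_equal(nrow(find_motif_sites("ACACACACAC")), 0)
  # the motif pair is closed under reverse complement, so a forward scan
  # covers both strands
  expect_equal(reverse_complement("CCAGG"), "CCTGG")
})

test_that("homopolymer runs are maximal and thresholded", {
  hp <- find_homopolymers("ACCCGT")
  expect_equal(hp$start, 1L)
  expect_equal(hp$length, 3L)
  expect_equal(hp$base, "C")
  expect_equal(find_homopolymers("AAAAA"),
               tibble::tibble(start = 0L, length = 5L, base = "A"))
  expect_equal(nrow(find_homopolymers("ACGT")), 0)
  expect_equal(nrow(find_homopolymers("AACCGGTT", min_len = 2)), 4)
})

test_that("error extraction splits mismatch runs and keeps gap runs whole", {
  withr::local_seed(52)
  ref <- random_seq(500)
  perfect <- align_banded(ref, ref)
  expect_equal(nrow(extract_errors(perfect, ref, ref)), 0)

  # 3 matches, 2 mismatches, 3 matches
  q <- paste0(substring(ref, 1, 3), "TT", substring(ref, 6, 8))
  r <- substring(ref, 1, 8)
  if (substring(r, 4, 5) == "TT") r <- paste0(substring(r, 1, 3), "AA",
                                              substring(r, 6, 8))
  aln <- align_banded(q, r)
  ev <- extract_errors(aln, r, q)
  subs <- ev[ev$kind == "substitution", ]
  expect_equal(nrow(subs), 2)
  expect_equal(subs$ref_pos, c(3L, 4L))

  # deletion of two bases is a single event carrying the full allele
  qd <- paste0(substring(ref, 1, 4), substring(ref, 7, 10))
  rd <- substring(ref, 1, 10)
  alnd <- align_banded(qd, rd)
  evd <- extract_errors(alnd, rd, qd)
  dels <- evd[evd$kind == "deletion", ]
  expect_equal(nrow(dels), 1)
  expect_equal(nchar(dels$ref_allele), 2)
})

test_that("classification follows Dcm > homopolymer > plain precedence", {
  ref <- "AACCAGGTTCCCCAGT"
  sites <- find_motif_sites(ref)   # CCAGG at [2, 7)
  runs <- find_homopolymers(ref)   # CCCC at [9, 13)

  ev <- tibble::tibble(
    ref_pos = c(3L, 10L, 14L, 4L, 9L),
    kind = c("substitution", "deletion", "substitution", "deletion", "insertion"),
    ref_allele = c("C", "C", "G", "A", ""),
    alt_allele = c("T", "", "A", "", "C"))
  cl <- classify_errors(ev, sites, runs)
  expect_equal(cl$klass,
               c("dcm",                   # inside the motif interval
                 "homopolymer_deletion",  # removes a C from CCCC
                 "substitution",          # plain context
                 "dcm",                   # indel touching the motif wins
                 "homopolymer_insertion")) # C inserted at the run flank

  # insertions adjacent to either flank of a run qualify
  ins_right <- tibble::tibble(ref_pos = 13L, kind = "insertion",
                              ref_allele = "", alt_allele = "CC")
  expect_equal(classify_errors(ins_right, sites, runs)$klass,
               "homopolymer_insertion")
  # a non-matching inserted base does not
  ins_other <- tibble::tibble(ref_pos = 13L, kind = "insertion",
                              ref_allele = "", alt_allele = "T")
  expect_equal(classify_errors(ins_other, sites, runs)$klass, "insertion")
})

test_that("every event gets exactly one class and counts are conserved", {
  cfg <- simulation_config(genome_bp = 20000, depth = 1, seed = 53)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  ref <- truth$reference
  sites <- find_motif_sites(ref)
  runs <- find_homopolymers(ref)
  idx <- ref_index(ref, circular = TRUE)
  aln <- align_reads(sim$reads, idx)
  all_events <- list()
  for (i in which(aln$aligned)) {
    q <- sim$reads$seq[[i]]
    if (aln$strand[[i]] == "-") q <- reverse_complement(q)
    ev <- extract_errors(aln[i, ], ref$seq[[1]], q, wrap_len = nchar(ref$seq[[1]]))
    all_events[[length(all_events) + 1]] <- ev
  }
  events <- dplyr::bind_rows(all_events)
  expect_gt(nrow(events), 100)
  cl <- classify_errors(events, sites, runs)
  expect_true(all(cl$klass %in% c("dcm", "homopolymer_insertion",
                                  "homopolymer_deletion", "insertion",
                                  "deletion", "substitution")))
  prof <- error_profile(cl, nchar(ref$seq[[1]]))
  expect_equal(prof$total_errors, nrow(events))
  expect_equal(sum(prof$table$count), nrow(events))
})

test_that("dcm classification is complete and exclusive on planted truth", {
  cfg <- simulation_config(genome_bp = 30000, seed = 54)
  truth <- generate_reference(cfg)
  ref <- truth$reference
  sites <- find_motif_sites(ref)
  runs <- find_homopolymers(ref)
  # an event at the methylated C of every planted site
  planted <- tibble::tibble(ref_pos = truth$motif_sites$start + 1L,
                            kind = "substitution", ref_allele = "C",
                            alt_allele = truth$motif_sites$miscall_base)
  expect_true(all(classify_errors(planted, sites, runs)$klass == "dcm"))
  # no event outside the motif intervals may be called dcm
  rng <- attr(sites, "ranges")
  withr::local_seed(54)
  outside <- setdiff(sample(0:(nchar(ref$seq[[1]]) - 1), 500),
                     unlist(mapply(seq, sites$start, sites$end - 1,
                                   SIMPLIFY = FALSE)))
  ev <- tibble::tibble(ref_pos = as.integer(outside), kind = "substitution",
                       ref_allele = "A", alt_allele = "C")
  expect_false(any(classify_errors(ev, sites, runs)$klass == "dcm"))
})

test_that("event lengths over alignment columns reproduce BLAST identity", {
  withr::local_seed(55)
  for (r in 1:25) {
    ref <- random_seq(800)
    q <- mutate_seq(ref, sample(5:40, 1))
    aln <- align_banded(q, ref, band = 128)
    ev <- extract_errors(aln, ref, q)
    event_bases <- sum(pmax(nchar(ev$ref_allele), nchar(ev$alt_allele),
                            as.integer(nrow(ev) > 0)))
    if (nrow(ev)) {
      event_bases <- sum(pmax(nchar(ev$ref_allele), nchar(ev$alt_allele), 1L))
    } else event_bases <- 0L
    cols <- aln$nmatch + aln$nmismatch + aln$nins + aln$ndel
    expect_equal(1 - event_bases / cols, blast_identity(aln), tolerance = 1e-9)
  }
})

test_that("error profiles report counts and per-100-bp rates", {
  empty <- error_profile(
    classify_errors(tibble::tibble(ref_pos = integer(), kind = character(),
                                   ref_allele = character(),
                                   alt_allele = character()),
                    find_motif_sites("ACGTACGTAA"), find_homopolymers("ACGTACGTAA")),
    10000)
  expect_equal(empty$total_errors, 0)
  expect_equal(empty$total_error_pct, 0)
  expect_equal(sum(empty$table$count), 0)
  expect_equal(nrow(empty$table), 6)

  ev <- tibble::tibble(ref_pos = c(10L, 20L, 30L, 40L, 50L),
                       kind = "substitution", ref_allele = "C",
                       alt_allele = "T",
                       klass = "dcm")
  prof <- error_profile(ev, 10000)
  expect_equal(prof$table$rate_per_100bp[prof$table$klass == "dcm"], 0.05)
  expect_equal(prof$total_errors, 5)
  expect_equal(prof$total_error_pct, 0.05)
  g <- glance(prof)
  expect_equal(g$total_errors, 5)
  expect_s3_class(tidy(prof), "tbl_df")
})
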