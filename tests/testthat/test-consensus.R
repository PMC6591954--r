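test_that("sequence rotation follows 0-based slicing and inverts", {
  expect_equal(rotate_sequence("ACGT", 1), "CGTA")
  expect_equal(rotate_sequence("ACGT", 0), "ACGT")
  expect_error(rotate_sequence("ACGT", 4), "range")
  expect_error(rotate_sequence("ACGT", -1), "range")
  withr::local_seed(41)
  s <- random_seq(500)
  for (k in c(1, 7, 250, 499)) {
    expect_equal(rotate_sequence(rotate_sequence(s, k), 500 - k), s)
  }
})

test_that("tiling replaces covered spans with read sequence", {
  withr::local_seed(42)
  ref <- random_seq(3000)
  idx <- ref_index(ref, circular = FALSE)

  # no reads: draft is the reference
  none <- align_reads(seq_tbl(character(), character())[0, ], idx)
  expect_equal(tile_reference(ref, none, seq_tbl(character(), character()),
                              circular = FALSE), ref)

  # one error-free read covering everything: draft is the reference
  full <- seq_tbl("full", ref)
  aln <- align_reads(full, idx)
  expect_equal(tile_reference(ref, aln, full, circular = FALSE), ref)

  # a single substitution carried by the covering read lands in the draft
  p <- 1500L
  mutated <- paste0(substring(ref, 1, p), "A" , substring(ref, p + 2, 3000))
  if (substring(ref, p + 1, p + 1) == "A") {
    mutated <- paste0(substring(ref, 1, p), "C", substring(ref, p + 2, 3000))
  }
  rd <- seq_tbl("mut", mutated)
  draft <- tile_reference(ref, align_reads(rd, idx), rd, circular = FALSE)
  diff <- which(strsplit(draft, "")[[1]] != strsplit(ref, "")[[1]])
  expect_equal(diff, p + 1L)
})

test_that("majority voting corrects draft errors and keeps systematic ones", {
  withr::local_seed(43)
  ref <- random_seq(1000)
  reads <- seq_tbl(c("a", "b", "c"), c(ref, ref, ref))
  draft <- mutate_seq(ref, 0)
  ch <- strsplit(ref, "")[[1]]
  err_pos <- sort(sample(100:900, 5))
  ch[err_pos] <- vapply(ch[err_pos],
                        function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                        character(1))
  draft <- paste0(ch, collapse = "")
  p <- consensus_params(circular = FALSE)
  polished <- polish_round(draft, reads, p)
  expect_equal(polished, ref)  # unanimous vote fixes all five

  # a substitution carried by >50% of reads is retained
  alt <- strsplit(ref, "")[[1]]
  alt[500] <- setdiff(c("A", "C", "G", "T"), alt[500])[1]
  alt_seq <- paste0(alt, collapse = "")
  sys_reads <- seq_tbl(c("a", "b", "c"), c(alt_seq, alt_seq, ref))
  polished2 <- polish_round(ref, sys_reads, p)
  expect_equal(substring(polished2, 500, 500), alt[500])

  # reads that do not align leave the draft untouched
  junk <- seq_tbl("junk", random_seq(500))
  expect_equal(polish_round(draft, junk, p), draft)
})

test_that("reference-guided assembly recovers the reference from clean reads", {
  withr::local_seed(44)
  ref <- random_seq(12000)
  reads <- tiling_reads(ref, 3000, 1000)  # depth ~3, full coverage
  p <- consensus_params(circular = FALSE, seed = 44)
  asm <- rebaler_lite(ref, reads, p)
  expect_equal(asm$seq[[1]], ref)

  # depth-1: the assembly carries the single read's basecalls
  alt <- strsplit(ref, "")[[1]]
  alt[6000] <- setdiff(c("A", "C", "G", "T"), alt[6000])[1]
  single <- seq_tbl("solo", paste0(alt, collapse = ""))
  asm1 <- rebaler_lite(ref, single, p)
  expect_equal(asm1$seq[[1]], single$seq[[1]])
})

test_that("noisy reads at depth 30 assemble to >99.9% identity", {
  cfg <- simulation_config(genome_bp = 20000, depth = 30, seed = 45)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  p <- consensus_params(seed = 45)
  asm <- rebaler_lite(truth$reference, sim$reads, p)
  idx <- ref_index(truth$reference, circular = TRUE)
  ci <- consensus_identity(chunk_assembly(asm), idx)
  expect_gt(ci$median_chunk_identity, 0.999)
})

test_that("iterative consensus is deterministic and exact on clean reads", {
  withr::local_seed(46)
  ref <- random_seq(15000)
  reads <- tiling_reads(ref, 3000, 600)
  p <- consensus_params(iterations = 3, circular = FALSE, seed = 46)
  asm <- iterative_consensus(ref, reads, p)
  expect_equal(asm$seq[[1]], ref)
  asm2 <- iterative_consensus(ref, reads, p)
  expect_identical(asm$seq, asm2$seq)
})

test_that("a systematic locus error carried by most reads survives assembly", {
  withr::local_seed(47)
  ref <- random_seq(8000)
  reads <- tiling_reads(ref, 2000, 250)
  alt_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  locus <- 4000L
  target <- substring(ref, locus, locus)
  carrier <- seq_len(nrow(reads)) %% 10 < 7  # ~70% of reads carry the error
  for (i in which(carrier)) {
    s <- reads$seq[[i]]
    start0 <- (i - 1) * 250  # tiling offset of read i
    lp <- locus - 1L - start0
    if (lp >= 0 && lp < nchar(s)) {
      substr(reads$seq[[i]], lp + 1, lp + 1) <- alt_base(target)
    }
  }
  p <- consensus_params(circular = FALSE, seed = 47)
  asm <- iterative_consensus(ref, reads, p)
  expect_equal(substring(asm$seq[[1]], locus, locus), alt_base(target))
})

test_that("circular rotation bookkeeping restores the canonical start", {
  cfg <- simulation_config(genome_bp = 15000, depth = 12, seed = 48)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  p <- consensus_params(iterations = 2, seed = 48)
  asm <- iterative_consensus(truth$reference, sim$reads, p)
  # canonical start: assembly begins where the reference begins
  expect_equal(substring(asm$seq[[1]], 1, 300),
               substring(truth$reference$seq[[1]], 1, 300))
})
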