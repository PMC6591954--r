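test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- simulation_config(genome_bp = 15000, depth = 5, seed = 61)
  t1 <- generate_reference(cfg)
  t2 <- generate_reference(cfg)
  expect_identical(t1$reference$seq, t2$reference$seq)
  expect_identical(t1$motif_sites, t2$motif_sites)
  s1 <- simulate_reads(t1, cfg)
  s2 <- simulate_reads(t2, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$ledger, s2$ledger)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  for (f in c("reference.fasta", "reads.fastq", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the generated reference carries exactly the recorded features", {
  cfg <- simulation_config(genome_bp = 50000, n_motif_sites = 100, seed = 62)
  truth <- generate_reference(cfg)
  ref <- truth$reference
  # motif truth is exact: every occurrence is recorded, nothing stray
  found <- find_motif_sites(ref)
  expect_equal(nrow(found), 100)
  expect_equal(found$start, truth$motif_sites$start)
  expect_equal(found$motif, truth$motif_sites$motif)
  # planted homopolymers exist as maximal runs of the recorded length
  runs <- find_homopolymers(ref)
  for (i in seq_len(nrow(truth$homopolymers))) {
    hp <- truth$homopolymers[i, ]
    hit <- runs[runs$start == hp$start & runs$base == hp$base, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$length, hp$length)
  }
})

test_that("realised GC tracks the target within 0.01 at 50 kbp", {
  for (s in 1:10) {
    cfg <- simulation_config(genome_bp = 50000, gc = 0.576, seed = 70 + s)
    ref <- generate_reference(cfg)$reference$seq[[1]]
    gc <- sum(strsplit(ref, "")[[1]] %in% c("G", "C")) / nchar(ref)
    expect_lt(abs(gc - 0.576), 0.01)
  }
})

test_that("error-free configurations emit exact reference substrings", {
  cfg <- simulation_config(genome_bp = 12000, depth = 3, sub_rate = 0,
                           ins_rate = 0, del_rate = 0, seed = 63)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  expect_equal(nrow(sim$ledger), 0)
  doubled <- strrep(truth$reference$seq[[1]], 2)
  for (i in seq_len(nrow(sim$reads))) {
    lay <- sim$layout[i, ]
    expected <- substring(doubled, lay$ref_start + 1,
                          lay$ref_start + lay$length)
    if (lay$strand == "-") expected <- reverse_complement(expected)
    expect_identical(sim$reads$seq[[i]], expected)
  }
})

test_that("replaying the ledger reconstructs every simulated read", {
  cfg <- simulation_config(genome_bp = 10000, depth = 4, dcm_error_rate = 0.7,
                           homopolymer_slip_rate = 0.6, seed = 64)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  doubled <- strrep(truth$reference$seq[[1]], 2)

  # independent replay: apply the logged events by direct string surgery,
  # descending position so indices stay valid
  replay <- function(read_id) {
    lay <- sim$layout[sim$layout$read_id == read_id, ]
    ev <- sim$ledger[sim$ledger$read_id == read_id, ]
    s <- substring(doubled, lay$ref_start + 1, lay$ref_start + lay$length)
    # descending position; at a tied position the base edit precedes the
    # junction insertion, and stacked insertions unwind in reverse order
    is_ins <- ev$kind == "insertion"
    ev <- ev[order(-ev$local_pos, is_ins, -seq_len(nrow(ev))), ]
    for (j in seq_len(nrow(ev))) {
      p <- ev$local_pos[[j]]
      if (ev$kind[[j]] == "substitution") {
        s <- paste0(substring(s, 1, p), ev$alt_allele[[j]],
                    substring(s, p + 2))
      } else if (ev$kind[[j]] == "deletion") {
        s <- paste0(substring(s, 1, p), substring(s, p + 2))
      } else {
        s <- paste0(substring(s, 1, p), ev$alt_allele[[j]],
                    substring(s, p + 1))
      }
    }
    if (lay$strand == "-") s <- reverse_complement(s)
    s
  }
  for (id in sim$reads$id) {
    expect_identical(sim$reads$seq[[which(sim$reads$id == id)]], replay(id),
                     label = id)
  }
})

test_that("pooled injected substitution frequency matches the configured rate", {
  cfg <- simulation_config(genome_bp = 20000, depth = 50,
                           read_len_mean = 2000, read_len_sd = 300,
                           sub_rate = 0.05, ins_rate = 0, del_rate = 0,
                           seed = 65)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  expect_gte(nrow(sim$reads), 450)
  total_bases <- sum(sim$layout$length)
  p_hat <- nrow(sim$ledger[sim$ledger$kind == "substitution", ]) / total_bases
  se <- sqrt(0.05 * 0.95 / total_bases)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("a certain Dcm miscall hits every covered planted site", {
  cfg <- simulation_config(genome_bp = 10000, depth = 5, n_motif_sites = 40,
                           sub_rate = 0, ins_rate = 0, del_rate = 0,
                           dcm_error_rate = 1.0, seed = 66)
  truth <- generate_reference(cfg)
  sim <- simulate_reads(truth, cfg)
  L <- cfg$genome_bp
  for (i in seq_len(nrow(sim$layout))) {
    lay <- sim$layout[i, ]
    local <- (truth$motif_sites$start - lay$ref_start) %% L
    covered <- sum(local >= 0 & local + 5 <= lay$length)
    hit <- sum(sim$ledger$read_id == lay$read_id &
                 sim$ledger$channel == "dcm")
    expect_equal(hit, covered)
  }
  # the miscall is at the methylated C and matches the site's fixed base
  dcm <- sim$ledger[sim$ledger$channel == "dcm", ]
  expect_true(all(dcm$ref_allele == "C"))
  site_base <- truth$motif_sites$miscall_base[
    match(dcm$ref_pos, truth$motif_sites$start + 1L)]
  expect_identical(dcm$alt_allele, site_base)
})

test_that("the expected consensus profile follows majority logic", {
  cfg_hi <- simulation_config(genome_bp = 30000, n_motif_sites = 100,
                              dcm_error_rate = 0.9, seed = 67)
  truth <- generate_reference(cfg_hi)
  prof_hi <- expected_profile(truth, cfg_hi)
  expect_equal(prof_hi$table$count[prof_hi$table$klass == "dcm"], 100)

  cfg_lo <- simulation_config(genome_bp = 30000, n_motif_sites = 100,
                              dcm_error_rate = 0.1, seed = 67)
  prof_lo <- expected_profile(truth, cfg_lo)
  expect_equal(prof_lo$total_errors, 0)

  # random channels contribute nothing at consensus level
  cfg_rand <- simulation_config(genome_bp = 30000, sub_rate = 0.05,
                                depth = 100, seed = 67)
  expect_equal(expected_profile(truth, cfg_rand)$total_errors, 0)

  # slips above the majority threshold appear with their fixed direction
  cfg_slip <- simulation_config(genome_bp = 30000,
                                homopolymer_slip_rate = 0.8, seed = 67)
  prof_slip <- expected_profile(truth, cfg_slip)
  tab <- prof_slip$table
  n_ins <- tab$count[tab$klass == "homopolymer_insertion"]
  n_del <- tab$count[tab$klass == "homopolymer_deletion"]
  expect_equal(n_ins + n_del, nrow(truth$homopolymers))
  expect_equal(n_ins, sum(truth$homopolymers$slip_dir > 0))
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(simulation_config(sub_rate = 1.5), "sub_rate")
  expect_error(simulation_config(genome_bp = 100), "genome_bp")
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(simulation_config(genome_bp = 1000, n_motif_sites = 500),
               "infeasible")
})
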