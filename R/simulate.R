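# Synthetic references and reads with the statistical structure the
# analysis assumes: a random error channel (i.i.d. substitutions and
# indels, outvoted by consensus at adequate depth) and two systematic
# channels (Dcm-motif miscalls and homopolymer length slips, shared across
# reads at fixed loci, hence able to survive into the consensus). Every
# injected event is logged so parameter-recovery tests can compare the
# pipeline's output against ground truth.

#' Simulation configuration
#'
#' Defaults describe a desk-scale bacterial-like benchmark: a 50 kbp
#' circular genome at 57.6% GC with 100 planted Dcm motif sites and a grid
#' of planted homopolymer runs, read at 40x depth with 5 kbp (sd 1.5 kbp)
#' reads carrying 5% random error (half substitutions, a quarter each
#' insertions and deletions). The systematic channels are off by default.
#'
#' @param genome_bp reference length in bp.
#' @param gc GC content in \[0, 1\].
#' @param n_motif_sites number of planted CCAGG/CCTGG sites (non-overlapping;
#'   no accidental motif occurrences remain outside the recorded sites).
#' @param homopolymer_spec data frame with columns `base`, `length`,
#'   `count` describing planted runs.
#' @param depth mean read depth.
#' @param read_len_mean,read_len_sd truncated-normal read length (bp).
#' @param sub_rate,ins_rate,del_rate per-base random-channel error rates.
#' @param dcm_error_rate probability that a read miscalls the methylated
#'   (second) C of each planted motif site it covers; the miscall base is a
#'   fixed property of the site, so rates above 0.5 survive majority-vote
#'   consensus.
#' @param homopolymer_slip_rate probability that a read changes a planted
#'   run's length by one; the direction is a fixed property of the run.
#' @param circular simulate a circular chromosome.
#' @param seed integer seed; identical configurations are byte-reproducible.
#' @return a `sim_config` object.
#' @export
simulation_config <- function(genome_bp = 50000L, gc = 0.576,
                              n_motif_sites = 100L,
                              homopolymer_spec = default_homopolymer_spec(),
                              depth = 40, read_len_mean = 5000L,
                              read_len_sd = 1500L,
                              sub_rate = 0.025, ins_rate = 0.0125,
                              del_rate = 0.0125,
                              dcm_error_rate = 0, homopolymer_slip_rate = 0,
                              circular = TRUE, seed = 1L) {
  rates <- c(gc = gc, sub_rate = sub_rate, ins_rate = ins_rate,
             del_rate = del_rate, dcm_error_rate = dcm_error_rate,
             homopolymer_slip_rate = homopolymer_slip_rate)
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) {
    abort(sprintf("rate out of [0, 1]: %s", paste(bad, collapse = ", ")))
  }
  if (genome_bp < 1000) abort("genome_bp must be >= 1000")
  if (depth <= 0) abort("depth must be positive")
  if (read_len_mean < 200) abort("read_len_mean must be >= 200")
  spec <- as_tibble(homopolymer_spec)
  if (!all(c("base", "length", "count") %in% names(spec))) {
    abort("homopolymer_spec needs columns base, length, count")
  }
  footprint <- 5L * n_motif_sites + sum(spec$length * spec$count) +
    8L * (n_motif_sites + sum(spec$count))
  if (footprint > 0.5 * genome_bp) {
    abort("infeasible planting: features would occupy over half the genome")
  }
  structure(list(genome_bp = as.integer(genome_bp), gc = gc,
                 n_motif_sites = as.integer(n_motif_sites),
                 homopolymer_spec = spec, depth = depth,
                 read_len_mean = as.integer(read_len_mean),
                 read_len_sd = as.integer(read_len_sd),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, dcm_error_rate = dcm_error_rate,
                 homopolymer_slip_rate = homopolymer_slip_rate,
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname simulation_config
#' @export
default_homopolymer_spec <- function() {
  tibble(base = rep(c("A", "C", "G", "T"), times = 3),
         length = rep(c(4L, 6L, 8L), each = 4),
         count = 3L)
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic reference with recorded features
#'
#' Draws a seeded random genome at the requested GC content, plants the
#' configured motif sites and homopolymer runs at non-overlapping recorded
#' positions, and patches any accidental CCAGG/CCTGG occurrence outside the
#' recorded sites so motif truth is exact. Planted runs are flanked by
#' differing bases so they are maximal, and their records reflect the final
#' patched sequence.
#'
#' @param config a [simulation_config()].
#' @return a `sim_truth` object: list with `reference` (one-row sequence
#'   tibble), `motif_sites` (`start`, `motif`, `miscall_base`),
#'   `homopolymers` (`start`, `length`, `base`, `slip_dir`) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    L <- config$genome_bp
    gc <- config$gc
    x <- sample(BASES, L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

    spec <- config$homopolymer_spec
    feats <- dplyr::bind_rows(
      tibble(type = "motif",
             len = rep(5L, config$n_motif_sites),
             base = NA_character_),
      tibble(type = rep("hp", sum(spec$count)),
             len = rep(spec$length, spec$count),
             base = rep(spec$base, spec$count))
    )
    if (nrow(feats)) feats <- feats[order(-feats$len), , drop = FALSE]

    occupied <- logical(L)
    starts <- integer(nrow(feats))  # 0-based
    for (f in seq_len(nrow(feats))) {
      len <- feats$len[[f]]
      placed <- FALSE
      for (try in seq_len(2000L)) {
        s <- sample.int(L - len - 6L, 1L) + 3L  # 1-based, 3 bp from the ends
        span <- (s - 3L):(s + len + 2L)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          starts[[f]] <- s - 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("infeasible planting: could not place all features")
    }

    motif_rows <- which(feats$type == "motif")
    motif_choice <- sample(c("CCAGG", "CCTGG"), length(motif_rows),
                           replace = TRUE)
    for (j in seq_along(motif_rows)) {
      s <- starts[[motif_rows[[j]]]]
      x[(s + 1L):(s + 5L)] <- strsplit(motif_choice[[j]], "")[[1]]
    }
    hp_rows <- which(feats$type == "hp")
    for (j in hp_rows) {
      s <- starts[[j]]; len <- feats$len[[j]]; b <- feats$base[[j]]
      x[(s + 1L):(s + len)] <- b
      others <- setdiff(BASES, b)
      if (s >= 1L && x[[s]] == b) x[[s]] <- sample(others, 1L)
      if (s + len + 1L <= L && x[[s + len + 1L]] == b) {
        x[[s + len + 1L]] <- sample(others, 1L)
      }
    }

    # patch accidental motif occurrences (middle base -> C never recreates
    # or spawns a motif; rescan until clean)
    recorded <- sort(starts[motif_rows])
    for (pass in seq_len(20L)) {
      seq_str <- paste0(x, collapse = "")
      found <- sort(c(find_fixed(seq_str, "CCAGG"), find_fixed(seq_str, "CCTGG")))
      stray <- setdiff(found, recorded)
      if (!length(stray)) break
      if (pass == 20L) abort("motif patching did not converge")
      x[stray + 3L] <- "C"
    }
    seq_str <- paste0(x, collapse = "")

    motif_sites <- tibble(
      start = starts[motif_rows],
      motif = motif_choice,
      miscall_base = sample(c("A", "G", "T"), length(motif_rows),
                            replace = TRUE)
    )
    motif_sites <- motif_sites[order(motif_sites$start), , drop = FALSE]

    # planted run records reflect the final sequence (a patch adjacent to a
    # run can extend it)
    all_runs <- find_homopolymers(seq_str, min_len = 2L)
    hp_records <- lapply(hp_rows, function(j) {
      s <- starts[[j]]
      hit <- all_runs[all_runs$start <= s &
                        s < all_runs$start + all_runs$length &
                        all_runs$base == feats$base[[j]], , drop = FALSE]
      hit[1, c("start", "length", "base")]
    })
    homopolymers <- dplyr::bind_rows(hp_records)
    if (nrow(homopolymers)) {
      homopolymers <- dplyr::distinct(homopolymers)
      homopolymers$slip_dir <- sample(c(-1L, 1L), nrow(homopolymers),
                                      replace = TRUE)
      homopolymers <- homopolymers[order(homopolymers$start), , drop = FALSE]
    } else {
      homopolymers <- tibble(start = integer(), length = integer(),
                             base = character(), slip_dir = integer())
    }

    structure(list(reference = seq_tbl("sim_ref", seq_str),
                   motif_sites = motif_sites,
                   homopolymers = homopolymers,
                   config = config),
              class = "sim_truth")
  })
}

# 0-based start positions of fixed-pattern occurrences
find_fixed <- function(seq, pattern) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (hits[[1]] == -1L) integer() else as.integer(hits) - 1L
}

#' Simulate reads from a synthetic reference
#'
#' Read start positions are uniform (wrapping for circular genomes),
#' lengths truncated-normal, strands random. The random channel applies
#' i.i.d. substitutions/insertions/deletions at the configured rates; the
#' Dcm channel miscalls the methylated C of each covered planted motif site
#' with probability `dcm_error_rate`; the homopolymer channel perturbs each
#' covered planted run's length by its fixed direction with probability
#' `homopolymer_slip_rate`. Every injected event is logged with its channel.
#' FASTQ-style qualities are uniform per read, derived from the read's
#' realised identity.
#'
#' @param truth a `sim_truth` from [generate_reference()].
#' @param config the matching [simulation_config()].
#' @return a list with `reads` (sequence tibble), `ledger` (one row per
#'   injected event: `read_id`, `channel`, `kind`, `local_pos`, `ref_pos`,
#'   `ref_allele`, `alt_allele`) and `layout` (`read_id`, `ref_start`,
#'   `length`, `strand`, `qscore`).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$depth <= 0) abort("depth must be positive")
  ref <- truth$reference$seq[[1]]
  L <- nchar(ref)
  source_seq <- if (config$circular) paste0(ref, ref) else ref

  with_seed(config$seed + 1003L, {
    n <- max(1L, as.integer(round(config$depth * L / config$read_len_mean)))
    lens <- as.integer(pmin(L, pmax(200L, round(
      rnorm(n, config$read_len_mean, config$read_len_sd)))))
    starts <- if (config$circular) {
      sample.int(L, n, replace = TRUE) - 1L
    } else {
      as.integer(floor(runif(n, 0, L - lens + 1)))
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)

    ids <- sprintf("read_%05d", seq_len(n))
    seqs <- character(n)
    quals <- vector("list", n)
    ledgers <- vector("list", n)

    for (i in seq_len(n)) {
      sim <- simulate_one_read(ref, source_seq, L, starts[[i]], lens[[i]],
                               strands[[i]], truth, config)
      seqs[[i]] <- sim$seq
      quals[[i]] <- rep(sim$qscore, nchar(sim$seq))
      if (nrow(sim$events)) {
        sim$events$read_id <- ids[[i]]
        ledgers[[i]] <- sim$events
      }
    }

    ledger <- dplyr::bind_rows(ledgers)
    if (!nrow(ledger)) {
      ledger <- tibble(read_id = character(), channel = character(),
                       kind = character(), local_pos = integer(),
                       ref_pos = integer(), ref_allele = character(),
                       alt_allele = character())
    } else {
      ledger <- ledger[, c("read_id", "channel", "kind", "local_pos",
                           "ref_pos", "ref_allele", "alt_allele")]
    }
    list(reads = seq_tbl(ids, seqs, quals),
         ledger = ledger,
         layout = tibble(read_id = ids, ref_start = starts, length = lens,
                         strand = strands,
                         qscore = vapply(quals, function(q) q[[1]], numeric(1))))
  })
}

simulate_one_read <- function(ref, source_seq, L, start, len, strand,
                              truth, config) {
  chars <- strsplit(substring(source_seq, start + 1L, start + len), "")[[1]]
  ev <- list()

  # Dcm channel: miscall the methylated C (offset 1 in CCWGG) of covered
  # planted sites; the miscall base is a property of the site
  ms <- truth$motif_sites
  if (nrow(ms) && config$dcm_error_rate > 0) {
    local <- site_local(ms$start, 5L, start, len, L, config$circular)
    cover <- which(!is.na(local))
    hit <- cover[runif(length(cover)) < config$dcm_error_rate]
    if (length(hit)) {
      pos <- local[hit] + 1L  # second C of the motif
      ev$dcm <- tibble(channel = "dcm", kind = "substitution",
                       local_pos = pos,
                       ref_allele = chars[pos + 1L],
                       alt_allele = ms$miscall_base[hit])
    }
  }

  # homopolymer channel: change a covered planted run's length by its fixed
  # direction
  hp <- truth$homopolymers
  if (nrow(hp) && config$homopolymer_slip_rate > 0) {
    local <- site_local(hp$start, hp$length, start, len, L, config$circular)
    cover <- which(!is.na(local))
    hit <- cover[runif(length(cover)) < config$homopolymer_slip_rate]
    if (length(hit)) {
      ins_hit <- hit[hp$slip_dir[hit] > 0]
      del_hit <- hit[hp$slip_dir[hit] < 0]
      if (length(ins_hit)) {
        ev$hp_ins <- tibble(channel = "homopolymer", kind = "insertion",
                            local_pos = local[ins_hit],
                            ref_allele = "",
                            alt_allele = hp$base[ins_hit])
      }
      if (length(del_hit)) {
        ev$hp_del <- tibble(channel = "homopolymer", kind = "deletion",
                            local_pos = local[del_hit],
                            ref_allele = hp$base[del_hit],
                            alt_allele = "")
      }
    }
  }

  taken_sub <- unlist(lapply(ev, function(e) e$local_pos[e$kind != "insertion"]))
  taken_ins <- unlist(lapply(ev, function(e) e$local_pos[e$kind == "insertion"]))

  # random channel
  sub_pos <- setdiff(which(runif(len) < config$sub_rate) - 1L, taken_sub)
  if (length(sub_pos)) {
    alt <- vapply(sub_pos, function(p) {
      sample(setdiff(BASES, chars[[p + 1L]]), 1L)
    }, character(1))
    ev$sub <- tibble(channel = "random", kind = "substitution",
                     local_pos = as.integer(sub_pos),
                     ref_allele = chars[sub_pos + 1L], alt_allele = alt)
  }
  del_pos <- setdiff(which(runif(len) < config$del_rate) - 1L,
                     c(taken_sub, sub_pos))
  if (length(del_pos)) {
    ev$del <- tibble(channel = "random", kind = "deletion",
                     local_pos = as.integer(del_pos),
                     ref_allele = chars[del_pos + 1L], alt_allele = "")
  }
  ins_pos <- setdiff(which(runif(len + 1L) < config$ins_rate) - 1L, taken_ins)
  if (length(ins_pos)) {
    ev$ins <- tibble(channel = "random", kind = "insertion",
                     local_pos = as.integer(ins_pos), ref_allele = "",
                     alt_allele = sample(BASES, length(ins_pos),
                                         replace = TRUE))
  }

  events <- dplyr::bind_rows(ev)
  if (!nrow(events)) {
    events <- tibble(channel = character(), kind = character(),
                     local_pos = integer(), ref_allele = character(),
                     alt_allele = character())
  }
  out <- apply_events(chars, events)

  n_sub <- sum(events$kind == "substitution")
  n_del <- sum(events$kind == "deletion")
  n_ins <- sum(nchar(events$alt_allele[events$kind == "insertion"]))
  identity <- (len - n_sub - n_del) / (len + n_ins)
  qscore <- max(2L, min(60L, as.integer(round(identity_to_qscore(identity)))))

  read_seq <- if (strand == "-") reverse_complement(out) else out
  events$ref_pos <- if (config$circular) {
    as.integer((start + events$local_pos) %% L)
  } else {
    as.integer(start + events$local_pos)
  }
  list(seq = read_seq, qscore = qscore, events = events)
}

# local 0-based start for each feature if fully covered by the read span,
# NA otherwise
site_local <- function(feat_start, feat_len, start, len, L, circular) {
  local <- feat_start - start
  if (circular) local <- local %% L
  ifelse(local >= 0 & local + feat_len <= len, local, NA_integer_)
}

# apply substitution/deletion/insertion events (local, 0-based; insertions
# land before local_pos) to a character vector
apply_events <- function(chars, events) {
  len <- length(chars)
  if (!nrow(events)) return(paste0(chars, collapse = ""))
  keep <- rep(TRUE, len)
  subs <- events[events$kind == "substitution", , drop = FALSE]
  if (nrow(subs)) chars[subs$local_pos + 1L] <- subs$alt_allele
  dels <- events[events$kind == "deletion", , drop = FALSE]
  if (nrow(dels)) keep[dels$local_pos + 1L] <- FALSE
  ins <- events[events$kind == "insertion", , drop = FALSE]
  ins_before <- rep("", len + 1L)
  if (nrow(ins)) {
    agg <- tapply(ins$alt_allele, ins$local_pos, paste0, collapse = "")
    ins_before[as.integer(names(agg)) + 1L] <- as.character(agg)
  }
  body <- paste0(ins_before[seq_len(len)], ifelse(keep, chars, ""))
  paste0(paste0(body, collapse = ""), ins_before[[len + 1L]])
}

#' Expected consensus error profile under majority voting
#'
#' Systematic channels with per-read rate above 0.5 place their planted
#' sites in the consensus (majority logic); the random channel contributes
#' approximately nothing at adequate depth. Used as the oracle for
#' end-to-end parameter-recovery tests.
#'
#' @inheritParams simulate_reads
#' @return an [error_profile()] object.
#' @export
expected_profile <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  ref <- truth$reference
  ev <- list()
  if (config$dcm_error_rate > 0.5 && nrow(truth$motif_sites)) {
    ev$dcm <- tibble(ref_pos = truth$motif_sites$start + 1L,
                     kind = "substitution",
                     ref_allele = "C",
                     alt_allele = truth$motif_sites$miscall_base)
  }
  if (config$homopolymer_slip_rate > 0.5 && nrow(truth$homopolymers)) {
    hp <- truth$homopolymers
    ev$hp <- tibble(ref_pos = hp$start,
                    kind = ifelse(hp$slip_dir > 0, "insertion", "deletion"),
                    ref_allele = ifelse(hp$slip_dir > 0, "", hp$base),
                    alt_allele = ifelse(hp$slip_dir > 0, hp$base, ""))
  }
  events <- dplyr::bind_rows(ev)
  if (!nrow(events)) {
    events <- tibble(ref_pos = integer(), kind = character(),
                     ref_allele = character(), alt_allele = character())
  }
  classified <- classify_errors(events, find_motif_sites(ref),
                                find_homopolymers(ref))
  error_profile(classified, nchar(ref$seq[[1]]))
}
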