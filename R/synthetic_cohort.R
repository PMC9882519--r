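#' @title Synthetic tumour/normal cohort generation
#'
#' @description
#' Generates cohorts that emulate the statistical structures the
#' landscape analyses assume -- recurrent arm-level aneuploidy,
#' chromothripsis-like shattered regions with oscillating copy number,
#' 17p-like CN-LOH, TP53 hit-mechanism mixes at configurable VAF,
#' focal deletions sharing a minimally-deleted core, telomeric reads
#' with variant repeats, and interstitial telomere insertions -- with a
#' complete per-sample ground truth. The generative distributions are
#' stand-ins chosen for plausibility (the real cohorts were observed,
#' not sampled from a model); they are documented in the methods
#' vignette and everything is configurable.
#'
#' Reproducibility contract: one master integer seed; every
#' (sample, stage) pair derives its own RNG stream by stable hashing,
#' so adding a sample never perturbs the draws of another.
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' Defaults express the study conditions of a 42-sample TP53-mutated
#' AML/MDS cohort with an 18-sample CBF AML comparator on the toy
#' genome: arm-loss probabilities emulating the recurrent 5q/7q-like
#' losses, 60% chromothripsis prevalence, the published TP53
#' hit-mechanism mix (22:11:4:4:1 for SNV+loss, SNV+CN-LOH, two SNVs,
#' SNV+SV-disruption, monoallelic), 45% focal-deletion prevalence over
#' a 2.75-Mb shared core, telomere shortening of 226 TRPM in the CBF
#' cohort versus 2.5 in TP53 samples, an elevated singleton TTTGGG
#' fraction in TP53 tumours, and 31% interstitial-insertion prevalence.
#'
#' @param seed master integer seed.
#' @param n_tp53,n_cbf cohort sizes.
#' @param dict toy reference dictionary.
#' @param purity_range uniform purity draw bounds.
#' @param baf_spacing,baf_depth heterozygous-site spacing (bp) and
#'   per-site read depth.
#' @param aneuploidy_spec data.frame `arm, loss_prob, gain_prob`.
#' @param chromothripsis_spec list: `prob`, `second_event_prob`,
#'   `bp_range`, `massive_frac` (fraction of carriers whose first event
#'   uses `massive_bp_range`, yielding >100-SV clusters),
#'   `chrom_weights`, `allowed_arms`, `region_mb`, `min_seg`,
#'   `third_state_prob`, `bnd_prob`.
#' @param cnloh_spec list: `prob`, `arms` (extra CN-LOH beyond the TP53
#'   mechanism).
#' @param tp53_spec list: `locus`, `mech_probs`, `vaf_depth`.
#' @param mdr_spec list: `core`, `arm`, `prob`, `max_flank`.
#' @param sv_background list: `rate_tp53`, `rate_cbf`, `size_range`,
#'   `bnd_prob`, `ins_prob`.
#' @param telomere_spec list: `read_length`, `n_reads`, `normal_trpm`,
#'   `shortening_tp53`, `shortening_cbf`, `tvr_base`,
#'   `tvr_tp53_tumor`, `gc_probs`, `frac_gc_matched`.
#' @param insertion_spec list: `prob_tp53`, `prob_cbf`, `extra_prob`,
#'   `n_support`, `clip_len`, `near_sv_prob`, `near_sv_max`,
#'   `germline_prob`.
#' @param emit_reads generate SAM-style reads (disable for
#'   segment-level studies at scale).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_tp53 = 42, n_cbf = 18,
                       dict = toy_genome(),
                       purity_range = c(0.4, 0.95),
                       baf_spacing = 4e4, baf_depth = 40,
                       aneuploidy_spec = NULL,
                       chromothripsis_spec = NULL,
                       cnloh_spec = NULL,
                       tp53_spec = NULL,
                       mdr_spec = NULL,
                       sv_background = NULL,
                       telomere_spec = NULL,
                       insertion_spec = NULL,
                       emit_reads = TRUE) {
  if (is.null(aneuploidy_spec)) {
    aneuploidy_spec <- data.frame(
      arm = c("chrT1q", "chrT2q", "chrT2p", "chrT1p", "chrT3q"),
      loss_prob = c(0.80, 0.55, 0.00, 0.05, 0.10),
      gain_prob = c(0.00, 0.00, 0.20, 0.05, 0.00))
  }
  if (is.null(chromothripsis_spec)) {
    chromothripsis_spec <- list(
      prob = 0.6, second_event_prob = 0.5,
      bp_range = c(44, 190),
      satellite_bp_range = c(24, 80),
      massive_frac = 8 / 25, massive_bp_range = c(210, 300),
      chrom_weights = c(chrT1 = 0.45, chrT2 = 0.20, chrT3 = 0.25,
                        chrT4 = 0.10),
      allowed_arms = list(chrT1 = c("p", "q"), chrT2 = c("p", "q"),
                          chrT3 = "q", chrT4 = "q"),
      region_mb = 8, min_seg = 1e3, third_state_prob = 0.15,
      bnd_prob = 0.5)
  }
  if (is.null(cnloh_spec)) {
    cnloh_spec <- list(prob = 0.10, arms = "chrT1p")
  }
  if (is.null(tp53_spec)) {
    tp53_spec <- list(
      locus = tp53_locus_toy(),
      mech_probs = c(snv_loss = 22, snv_cnloh = 11, two_snv = 4,
                     sv_disruption = 4, monoallelic = 1) / 42,
      vaf_depth = 100)
  }
  if (is.null(mdr_spec)) {
    mdr_spec <- list(core = mdr_core_default(), arm = "chrT4p",
                     prob = 0.45, max_flank = 4e5)
  }
  if (is.null(sv_background)) {
    sv_background <- list(rate_tp53 = 15, rate_cbf = 5,
                          size_range = c(1e4, 1e6),
                          bnd_prob = 0.12, ins_prob = 0.05)
  }
  if (is.null(telomere_spec)) {
    telomere_spec <- list(
      read_length = 102, n_reads = 4000, normal_trpm = 3000,
      shortening_tp53 = 2.5, shortening_cbf = 226,
      tvr_base = c(TCAGGG = 0.02, TGAGGG = 0.02, TTGGGG = 0.01,
                   TTTGGG = 0.005),
      tvr_tp53_tumor = c(TCAGGG = 0.02, TGAGGG = 0.02, TTGGGG = 0.01,
                         TTTGGG = 0.02),
      gc_probs = c(0.40, 0.50), frac_gc_matched = 0.35)
  }
  if (is.null(insertion_spec)) {
    insertion_spec <- list(prob_tp53 = 13 / 42, prob_cbf = 0,
                           extra_prob = 4 / 13, n_support = 5,
                           clip_len = 48, aligned_len = 54,
                           near_sv_prob = 0.68, near_sv_max = 1e4,
                           germline_prob = 0.2)
  }
  check_that(all(aneuploidy_spec$loss_prob >= 0 &
                   aneuploidy_spec$loss_prob <= 1 &
                   aneuploidy_spec$gain_prob >= 0 &
                   aneuploidy_spec$gain_prob <= 1),
             "aneuploidy probabilities must be in [0,1]")
  check_that(sum(telomere_spec$tvr_base) <= 1 &&
               sum(telomere_spec$tvr_tp53_tumor) <= 1,
             "TVR composition fractions must sum to at most 1")
  check_that(telomere_spec$read_length >= 6,
             "telomere read length must be at least 6")
  structure(list(
    seed = seed, n_tp53 = n_tp53, n_cbf = n_cbf, dict = dict,
    purity_range = purity_range, baf_spacing = baf_spacing,
    baf_depth = baf_depth, aneuploidy_spec = aneuploidy_spec,
    chromothripsis_spec = chromothripsis_spec, cnloh_spec = cnloh_spec,
    tp53_spec = tp53_spec, mdr_spec = mdr_spec,
    sv_background = sv_background, telomere_spec = telomere_spec,
    insertion_spec = insertion_spec, emit_reads = emit_reads
  ), class = "sim_config")
}

# ------------------------------------------------- piecewise CN states ---

# pieces: data.frame(start, end, total, major, minor); override [s,e)
apply_state <- function(pieces, s, e, total, major, minor) {
  out <- list()
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    if (p$end <= s || p$start >= e) {
      out[[length(out) + 1]] <- p
      next
    }
    if (p$start < s) {
      out[[length(out) + 1]] <- data.frame(start = p$start, end = s,
                                           total = p$total, major = p$major,
                                           minor = p$minor)
    }
    if (p$end > e) {
      out[[length(out) + 1]] <- data.frame(start = e, end = p$end,
                                           total = p$total, major = p$major,
                                           minor = p$minor)
    }
  }
  out[[length(out) + 1]] <- data.frame(start = s, end = e, total = total,
                                       major = major, minor = minor)
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# splice a whole block of pieces into [s,e) in one pass (used for
# chromothripsis segmentations, which can carry hundreds of pieces)
splice_region <- function(pieces, new_pieces) {
  s <- min(new_pieces$start)
  e <- max(new_pieces$end)
  keep <- pieces[pieces$end <= s | pieces$start >= e, , drop = FALSE]
  left <- pieces[pieces$start < s & pieces$end > s, , drop = FALSE]
  if (nrow(left)) left <- transform(left[1, ], end = s)
  right <- pieces[pieces$start < e & pieces$end > e, , drop = FALSE]
  if (nrow(right)) right <- transform(right[nrow(right), ], start = e)
  res <- rbind(keep, left, right, new_pieces)
  res[order(res$start), , drop = FALSE]
}

state_for_total <- function(total) {
  # conventional allele split for integer totals
  switch(as.character(total),
         "0" = c(0, 0), "1" = c(1, 0), "2" = c(1, 1), "3" = c(2, 1),
         "4" = c(2, 2), c(ceiling(total / 2), floor(total / 2)))
}

# ----------------------------------------------- chromothripsis event ----

chords_all_connected <- function(a, b) {
  m <- length(a)
  if (m < 2) return(FALSE)
  cross <- outer(seq_len(m), seq_len(m), function(i, j) {
    (a[i] < a[j] & a[j] < b[i] & b[i] < b[j]) |
      (a[j] < a[i] & a[i] < b[j] & b[j] < b[i])
  })
  seen <- logical(m)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(cross[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Simulate one chromothripsis-like event
#'
#' Draws `n_breakpoints` positions (minimum segment size respected)
#' within a bounded region, makes the resulting segments oscillate
#' between two copy-number states (or three when `n_states = 3`), and
#' rejoins the breakpoints as randomly paired fragments with
#' orientations drawn uniformly over the four join classes.
#' Random matchings are redrawn until the resulting chords form one
#' mutually interleaved cluster (guaranteed interleaving; a rotational
#' matching is the deterministic fallback). Uses the current RNG state.
#'
#' @param chrom chromosome name.
#' @param region_start,region_end bounded region (0-based half-open).
#' @param n_breakpoints number of breakpoints (>= 6).
#' @param n_states 2 or 3 oscillation states.
#' @param min_seg minimum fragment size (bp).
#' @param sv_prefix id prefix for the emitted SVs.
#' @return list with `pieces` (piecewise CN states over the region) and
#'   `svs` (SV table rows).
#' @export
simulate_chromothripsis_event <- function(chrom, region_start, region_end,
                                          n_breakpoints, n_states = 2,
                                          min_seg = 5e4,
                                          sv_prefix = "ct") {
  check_that(n_breakpoints >= 6, "need at least 6 breakpoints")
  span <- region_end - region_start
  check_that(span >= (n_breakpoints + 1) * min_seg,
             "region of %d bp too short for %d breakpoints at min segment %d",
             span, n_breakpoints, min_seg)
  free <- span - (n_breakpoints + 1) * min_seg
  cuts <- sort(stats::runif(n_breakpoints))
  pos <- round(region_start + min_seg * seq_len(n_breakpoints) + cuts * free)

  bounds <- c(region_start, pos, region_end)
  k <- length(bounds) - 1
  totals <- integer(k)
  for (i in seq_len(k)) {
    if (i %% 2 == 1) {
      totals[i] <- 2
    } else if (n_states == 2) {
      totals[i] <- 1
    } else {
      totals[i] <- sample(c(1, 3), 1)
    }
  }
  pieces <- do.call(rbind, lapply(seq_len(k), function(i) {
    st <- state_for_total(totals[i])
    data.frame(start = bounds[i], end = bounds[i + 1], total = totals[i],
               major = st[1], minor = st[2])
  }))

  m <- n_breakpoints %/% 2
  pairing <- NULL
  for (try in seq_len(200)) {
    perm <- sample(n_breakpoints, 2 * m)
    cand <- matrix(perm, ncol = 2)
    a <- pmin(pos[cand[, 1]], pos[cand[, 2]])
    b <- pmax(pos[cand[, 1]], pos[cand[, 2]])
    if (chords_all_connected(a, b)) {
      pairing <- cbind(a, b)
      break
    }
  }
  if (is.null(pairing)) {
    # rotational matching: chord i joins breakpoints i and i + m,
    # giving mutually crossing chords
    a <- pos[seq_len(m)]
    b <- pos[seq_len(m) + m]
    pairing <- cbind(a, b)
  }
  orient <- matrix(c("+", "-", "-", "+", "+", "+", "-", "-"),
                   ncol = 2, byrow = TRUE)
  oi <- sample(4, m, replace = TRUE)
  svclass <- c("DEL", "DUP", "INV", "INV")[oi]
  svs <- data.frame(
    sv_id = sprintf("%s_%s_%02d", sv_prefix, chrom, seq_len(m)),
    chrom1 = chrom, pos1 = pairing[, 1], strand1 = orient[oi, 1],
    chrom2 = chrom, pos2 = pairing[, 2], strand2 = orient[oi, 2],
    svclass = svclass, inserted_seq = NA_character_)
  list(pieces = pieces, svs = svs)
}

# -------------------------------------------------------- CN-LOH sim -----

#' Simulate copy-neutral LOH over a chromosome arm
#'
#' Total copy number stays 2 with the minor allele lost; heterozygous
#' sites show major-allele BAF around `(1 + rho)/2` (or its mirror)
#' with binomial sampling noise at the configured depth, while the
#' log2 coverage ratio stays at 0.
#'
#' @param arm list with `chrom, start, end` (e.g. [arm_interval()]).
#' @param purity tumour purity rho.
#' @param spacing,depth BAF site spacing (bp) and per-site depth.
#' @return list with `segments` (one CN-LOH segment) and `baf_sites`.
#' @export
simulate_cnloh <- function(arm, purity, spacing = 4e4, depth = 40) {
  seg <- data.frame(chrom = arm$chrom, start = arm$start, end = arm$end,
                    total_cn = 2, major_cn = 2, minor_cn = 0,
                    log2_ratio = stats::rnorm(1, 0, 0.02))
  pos <- seq(arm$start + spacing / 2, arm$end - 1, by = spacing)
  b_major <- (1 + purity) / 2
  is_major <- stats::runif(length(pos)) < 0.5
  b <- ifelse(is_major, b_major, 1 - b_major)
  baf <- stats::rbinom(length(pos), depth, b) / depth
  list(segments = seg,
       baf_sites = data.frame(chrom = arm$chrom, pos = pos, baf = baf,
                              depth = depth))
}

# ---------------------------------------------------- read generation ----

# n random reads of length L with per-base GC probability p
random_reads_gc <- function(n, L, p) {
  if (n == 0) return(character(0))
  letters <- sample(c("G", "C", "A", "T"), n * L, replace = TRUE,
                    prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
  long <- paste(letters, collapse = "")
  substring(long, (seq_len(n) - 1) * L + 1, seq_len(n) * L)
}

# n telomeric reads of length L as hexamer concatenations, TVRs placed
# i.i.d. per composition; about half are emitted reverse-complemented
telomeric_reads <- function(n, L, composition) {
  if (n == 0) return(character(0))
  n_hex <- ceiling(L / 6)
  hexes <- c(t_type_hexamer(), names(composition))
  probs <- c(1 - sum(composition), unname(composition))
  idx <- matrix(sample(length(hexes), n * n_hex, replace = TRUE,
                       prob = probs), nrow = n)
  hexmat <- matrix(hexes[idx], nrow = n)
  seqs <- do.call(paste0, as.data.frame(hexmat, stringsAsFactors = FALSE))
  seqs <- substring(seqs, 1, L)
  flip <- seq_len(n) %% 2 == 0
  seqs[flip] <- revcomp(seqs[flip])
  seqs
}

#' Simulate telomeric and background reads for one tissue
#'
#' Background (non-telomeric) reads are drawn with mixed GC so that
#' GC-window matching is exercised; their realised in-window count then
#' fixes the number of telomeric reads emitted so that the realised
#' TRPM matches `trpm` up to integer rounding (the planted content is
#' exact by construction, not a sampling target). Interstitial
#' insertions are emitted as soft-clipped reads (telomeric clip tails)
#' at the planted loci. Reads are assigned uniform random alignment
#' positions; telomere analytics only use position for clipped reads.
#'
#' @param n_reads background read count.
#' @param read_length read length (>= 6).
#' @param trpm target telomeric reads per GC-matched million.
#' @param tvr_composition named fractions per variant hexamer
#'   (remainder is t-type).
#' @param insertion_loci optional data.frame `chrom, pos` of clip loci.
#' @param insertion_support clipped reads per locus.
#' @param clip_len,aligned_len clipped and aligned bases of insertion
#'   reads.
#' @param gc_probs per-base GC probabilities of the two background
#'   components.
#' @param frac_gc_matched fraction of background reads drawn from the
#'   telomere-like GC component.
#' @param dict reference dictionary for read placement.
#' @param prefix read-name prefix.
#' @return list with `reads` (data.frame `qname, flag, chrom, pos,
#'   mapq, cigar, seq`) and `truth` (realised `n_telomeric`,
#'   `n_gc_matched`, `trpm`).
#' @export
simulate_telomere_reads <- function(n_reads, read_length = 102,
                                    trpm = 3000,
                                    tvr_composition = c(TTTGGG = 0.005),
                                    insertion_loci = NULL,
                                    insertion_support = 5,
                                    clip_len = 48, aligned_len = 54,
                                    gc_probs = c(0.40, 0.50),
                                    frac_gc_matched = 0.35,
                                    dict = toy_genome(), prefix = "r") {
  check_that(read_length >= 6, "read length must be at least 6")
  n_in <- round(n_reads * frac_gc_matched)
  bg <- c(random_reads_gc(n_reads - n_in, read_length, gc_probs[1]),
          random_reads_gc(n_in, read_length, gc_probs[2]))
  gc <- gc_fraction(bg)
  g_in <- sum(gc >= 0.48 & gc <= 0.52)

  ins_seqs <- character(0)
  ins_rows <- NULL
  if (!is.null(insertion_loci) && nrow(insertion_loci)) {
    n_ins <- nrow(insertion_loci) * insertion_support
    aligned <- random_reads_gc(n_ins, aligned_len, 0.40)
    tail_hex <- strrep(t_type_hexamer(), ceiling(clip_len / 6))
    ins_seqs <- paste0(aligned, substring(tail_hex, 1, clip_len))
    ins_rows <- data.frame(
      chrom = rep(insertion_loci$chrom, each = insertion_support),
      pos = rep(insertion_loci$pos, each = insertion_support) - aligned_len,
      cigar = sprintf("%dM%dS", aligned_len, clip_len))
  }
  n_ins_tel <- if (length(ins_seqs)) {
    # clip tails qualify as telomeric whenever they carry enough hexamers
    sum((clip_len %/% 6) >= ceiling(6 * nchar(ins_seqs) / 100))
  } else 0L

  # realised in-window background count fixes the telomeric read count
  n_tel <- round(trpm * g_in / (1e6 - trpm))
  tel <- telomeric_reads(n_tel, read_length, tvr_composition)

  seqs <- c(bg, tel, ins_seqs)
  n_all <- length(seqs)
  chrom_draw <- sample(dict$chroms$chrom, n_all, replace = TRUE,
                       prob = dict$chroms$length)
  pos_draw <- floor(stats::runif(n_all) *
                      (chrom_length(dict, chrom_draw) - read_length))
  cigar <- rep(sprintf("%dM", read_length), n_all)
  if (!is.null(ins_rows)) {
    tailidx <- (n_all - nrow(ins_rows) + 1):n_all
    chrom_draw[tailidx] <- ins_rows$chrom
    pos_draw[tailidx] <- ins_rows$pos
    cigar[tailidx] <- ins_rows$cigar
  }
  reads <- data.frame(
    qname = sprintf("%s_%06d", prefix, seq_len(n_all)),
    flag = 0L, chrom = chrom_draw, pos = pos_draw, mapq = 60L,
    cigar = cigar, seq = seqs)
  gc_all <- gc_fraction(seqs)
  g_in_all <- sum(gc_all >= 0.48 & gc_all <= 0.52)
  truth <- list(n_telomeric = n_tel + n_ins_tel,
                n_gc_matched = g_in_all,
                trpm = (n_tel + n_ins_tel) / g_in_all * 1e6)
  list(reads = reads, truth = truth)
}

# ------------------------------------------------------ cohort driver ----

#' Simulate a full tumour/normal cohort with ground truth
#'
#' Runs every per-sample generation stage (purity, arm aneuploidy, TP53
#' mechanism, focal deletions over the shared core, chromothripsis,
#' background SVs, BAF tracks, reads, insertions) under per-stage
#' derived seeds. When `out_dir` is given, the per-sample file set
#' (SEG/BAF TSV, BEDPE, VCF, SAM), a sample sheet, and `truth.json`
#' are written and the returned profiles reference those files.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `profiles` (list of [sample_profile()], each
#'   additionally carrying in-memory `tumor_reads`/`normal_reads` when
#'   reads are generated) and `truth` (per-sample ground-truth list
#'   plus `mdr_core`).
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  check_that(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  dict <- cfg$dict
  ids <- c(sprintf("TP53_%03d", seq_len(cfg$n_tp53)),
           sprintf("CBF_%03d", seq_len(cfg$n_cbf)))
  cohorts <- c(rep("TP53_AML", cfg$n_tp53), rep("CBF_AML", cfg$n_cbf))
  if (!length(ids)) {
    return(list(profiles = list(), truth = list(samples = list(),
                                                mdr_core = cfg$mdr_spec$core)))
  }

  # Event types are assigned as exact shuffled compositions at cohort
  # level: the emulated study is one fixed observed cohort, so the
  # mechanism mix, chromothripsis / focal-deletion / insertion
  # prevalences and the near-SV insertion fraction are planted at their
  # configured proportions exactly (largest-remainder rounding), not as
  # Bernoulli rates. All within-sample noise still uses per-sample
  # hashed streams.
  assignments <- cohort_assignments(cfg, ids, cohorts)

  profiles <- vector("list", length(ids))
  truths <- vector("list", length(ids))
  names(profiles) <- names(truths) <- ids
  for (i in seq_along(ids)) {
    res <- simulate_sample(ids[i], cohorts[i], cfg, assignments[[i]])
    profiles[[i]] <- res$profile
    truths[[i]] <- res$truth
  }
  truth <- list(samples = truths, mdr_core = cfg$mdr_spec$core,
                seed = cfg$seed)
  if (!is.null(out_dir)) {
    write_cohort(profiles, truth, out_dir, dict)
    profiles <- lapply(profiles, function(p) {
      p$tumor_reads_path <- file.path(out_dir, p$sample_id,
                                      "tumor.sam")
      p$normal_reads_path <- file.path(out_dir, p$sample_id,
                                       "normal.sam")
      p
    })
  }
  list(profiles = profiles, truth = truth)
}

# cohort-level event-type assignment (see simulate_cohort)
cohort_assignments <- function(cfg, ids, cohorts) {
  n <- length(ids)
  tp53_idx <- which(cohorts == "TP53_AML")
  n_t <- length(tp53_idx)
  assign <- replicate(n, list(mech = "wild_type", ct = FALSE,
                              ct_massive = FALSE,
                              mdr = FALSE, mdr_anchor = FALSE,
                              ins_n = 0L, ins_near = logical(0)),
                      simplify = FALSE)
  if (n_t == 0) return(assign)
  with_seed(derive_seed(cfg$seed, "cohort", "assignments"), {
    mech_counts <- largest_remainder(cfg$tp53_spec$mech_probs, n_t)
    mechs <- sample(rep(names(mech_counts), mech_counts))
    n_ct <- round(cfg$chromothripsis_spec$prob * n_t)
    ct_flags <- sample(seq_len(n_t) %in% seq_len(n_ct))
    # of the chromothripsis carriers, a fixed fraction gets a massive
    # (>100-SV) first event
    massive_flags <- logical(n_t)
    if (n_ct > 0) {
      n_massive <- round(cfg$chromothripsis_spec$massive_frac * n_ct)
      sel <- which(ct_flags)
      massive_flags[sample(sel, min(n_massive, length(sel)))] <- TRUE
    }
    mdr_flags <- sample(seq_len(n_t) %in% seq_len(
      round(cfg$mdr_spec$prob * n_t)))
    ins <- cfg$insertion_spec
    ins_counts <- integer(n_t)
    n_sel <- round(ins$prob_tp53 * n_t)
    if (n_sel > 0) {
      n_multi <- round(ins$extra_prob * n_sel)
      per_sel <- rep(1L, n_sel)
      if (n_multi > 0) {
        per_sel[seq_len(n_multi)] <- rep(c(2L, 3L), length.out = n_multi)
      }
      ins_counts[sample(n_t, n_sel)] <- sample(per_sel)
    }
    total_loci <- sum(ins_counts)
    near_pool <- logical(total_loci)
    if (total_loci > 0) {
      near_pool[seq_len(round(ins$near_sv_prob * total_loci))] <- TRUE
      near_pool <- sample(near_pool)
    }
    offset <- 0L
    anchor_done <- FALSE
    for (k in seq_len(n_t)) {
      i <- tp53_idx[k]
      nk <- ins_counts[k]
      assign[[i]] <- list(
        mech = mechs[k], ct = ct_flags[k], ct_massive = massive_flags[k],
        mdr = mdr_flags[k],
        mdr_anchor = mdr_flags[k] && !anchor_done,
        ins_n = nk,
        ins_near = if (nk > 0) near_pool[offset + seq_len(nk)] else logical(0))
      if (mdr_flags[k]) anchor_done <- TRUE
      offset <- offset + nk
    }
  })
  assign
}

simulate_sample <- function(id, cohort, cfg, assign) {
  dict <- cfg$dict
  stage_seed <- function(stage) derive_seed(cfg$seed, id, stage)
  purity <- with_seed(stage_seed("purity"),
                      stats::runif(1, cfg$purity_range[1],
                                   cfg$purity_range[2]))

  pieces <- lapply(seq_len(nrow(dict$chroms)), function(i) {
    data.frame(start = 0, end = dict$chroms$length[i], total = 2,
               major = 1, minor = 1)
  })
  names(pieces) <- dict$chroms$chrom
  truth <- list(sample_id = id, cohort = cohort, purity = purity,
                arm_events = data.frame(arm = character(),
                                        type = character()),
                cnloh_arms = character(0),
                tp53 = NULL, mdr_loss = NULL,
                chromothripsis = data.frame(chrom = character(),
                                            start = numeric(),
                                            end = numeric(),
                                            n_breakpoints = integer(),
                                            n_sv = integer(),
                                            n_states = integer()),
                insertions = data.frame(chrom = character(),
                                        pos = numeric()),
                telomere = list())
  svs <- list()

  # -- arm-level aneuploidy (TP53 cohort only; CBF stays near-diploid)
  if (cohort == "TP53_AML") {
    with_seed(stage_seed("arms"), {
      for (k in seq_len(nrow(cfg$aneuploidy_spec))) {
        row <- cfg$aneuploidy_spec[k, ]
        u <- stats::runif(1)
        type <- if (u < row$loss_prob) "loss" else {
          if (u < row$loss_prob + row$gain_prob) "gain" else "none"
        }
        if (type == "none") next
        arm <- arm_interval(dict, row$arm)
        tot <- if (type == "loss") 1 else 3
        st <- state_for_total(tot)
        pieces[[arm$chrom]] <- apply_state(pieces[[arm$chrom]], arm$start,
                                            arm$end, tot, st[1], st[2])
        truth$arm_events <- rbind(truth$arm_events,
                                   data.frame(arm = row$arm, type = type))
      }
      # occasional additional CN-LOH arm
      if (stats::runif(1) < cfg$cnloh_spec$prob) {
        arm_name <- sample(cfg$cnloh_spec$arms, 1)
        arm <- arm_interval(dict, arm_name)
        pieces[[arm$chrom]] <- apply_state(pieces[[arm$chrom]], arm$start,
                                            arm$end, 2, 2, 0)
        truth$cnloh_arms <- c(truth$cnloh_arms, arm_name)
      }
    })
  }

  # -- TP53 mechanism
  small_vars <- NULL
  if (cohort == "TP53_AML") {
    locus <- cfg$tp53_spec$locus
    arm17p <- arm_interval(dict, paste0(locus$chrom, "p"))
    with_seed(stage_seed("tp53"), {
      mech <- assign$mech
      draw_vaf <- function(expected) {
        v <- stats::rbinom(1, cfg$tp53_spec$vaf_depth, expected) /
          cfg$tp53_spec$vaf_depth
        max(v, 1 / cfg$tp53_spec$vaf_depth)
      }
      mk_snv <- function(vaf, offset) {
        data.frame(chrom = locus$chrom,
                   pos = round(locus$start + offset * (locus$end - locus$start)),
                   ref = sample(c("A", "C", "G", "T"), 1),
                   alt = NA_character_, vaf = vaf, gene = locus$gene,
                   effect = sample(c("missense", "stop_gained"), 1))
      }
      n_snv <- switch(mech, two_snv = 2, 1)
      vaf_expect <- switch(mech,
        snv_loss = purity / (2 - purity),
        snv_cnloh = purity,
        purity / 2)
      snvs <- do.call(rbind, lapply(seq_len(n_snv), function(k) {
        mk_snv(draw_vaf(vaf_expect), k / (n_snv + 1))
      }))
      snvs$alt <- vapply(snvs$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
      small_vars <- snvs
      if (mech == "snv_loss") {
        pieces[[locus$chrom]] <- apply_state(pieces[[locus$chrom]],
                                              arm17p$start, arm17p$end,
                                              1, 1, 0)
        truth$arm_events <- rbind(truth$arm_events,
                                   data.frame(arm = paste0(locus$chrom, "p"),
                                              type = "loss"))
      } else if (mech == "snv_cnloh") {
        pieces[[locus$chrom]] <- apply_state(pieces[[locus$chrom]],
                                              arm17p$start, arm17p$end,
                                              2, 2, 0)
        truth$cnloh_arms <- c(truth$cnloh_arms, paste0(locus$chrom, "p"))
      } else if (mech == "sv_disruption") {
        bend <- round(locus$start + 0.5 * (locus$end - locus$start))
        partner <- round(stats::runif(1, locus$end + 2e5, locus$end + 2e6))
        svs[[length(svs) + 1]] <- data.frame(
          sv_id = "tp53_disrupt", chrom1 = locus$chrom, pos1 = bend,
          strand1 = "+", chrom2 = locus$chrom, pos2 = partner,
          strand2 = "-", svclass = "DEL", inserted_seq = NA_character_)
      }
      truth$tp53 <- list(
        mechanism = mech,
        category = if (mech == "monoallelic") "MONOALLELIC" else "MULTI_HIT")
    })
  } else {
    truth$tp53 <- list(mechanism = "wild_type", category = "WILD_TYPE")
  }

  # -- focal deletion over the shared core
  if (assign$mdr) {
    core <- cfg$mdr_spec$core
    arm <- arm_interval(dict, cfg$mdr_spec$arm)
    with_seed(stage_seed("mdr"), {
      if (assign$mdr_anchor) {
        s <- core$start; e <- core$end
      } else {
        s <- core$start - stats::runif(1) *
          min(cfg$mdr_spec$max_flank, core$start - arm$start)
        e <- core$end + stats::runif(1) *
          min(cfg$mdr_spec$max_flank, arm$end - core$end)
      }
      pieces[[core$chrom]] <- apply_state(pieces[[core$chrom]], round(s),
                                           round(e), 1, 1, 0)
      truth$mdr_loss <- data.frame(chrom = core$chrom, start = round(s),
                                    end = round(e))
    })
  }

  # -- chromothripsis
  ct <- cfg$chromothripsis_spec
  if (cohort == "TP53_AML") {
    with_seed(stage_seed("chromothripsis"), {
      if (assign$ct) {
        n_events <- if (stats::runif(1) < ct$second_event_prob) 2 else 1
        chroms_hit <- sample(names(ct$chrom_weights), n_events,
                             prob = ct$chrom_weights)
        first_event <- TRUE
        for (ch in chroms_hit) {
          arm_letter <- sample(ct$allowed_arms[[ch]], 1)
          arm <- arm_interval(dict, paste0(ch, arm_letter))
          arm_len <- arm$end - arm$start
          region_len <- min(ct$region_mb * 1e6, round(0.8 * arm_len))
          r_start <- round(arm$start +
                             stats::runif(1) * (arm_len - region_len))
          bp_range <- if (assign$ct_massive && first_event) {
            ct$massive_bp_range
          } else if (first_event || is.null(ct$satellite_bp_range)) {
            ct$bp_range
          } else {
            # satellite events are smaller than the index event
            ct$satellite_bp_range
          }
          first_event <- FALSE
          n_bp <- sample(seq(bp_range[1], bp_range[2]), 1)
          n_bp <- min(n_bp, floor(region_len / ct$min_seg) - 1)
          n_states <- if (stats::runif(1) < ct$third_state_prob) 3 else 2
          ev <- simulate_chromothripsis_event(
            ch, r_start, r_start + region_len, n_bp,
            n_states = n_states, min_seg = ct$min_seg,
            sv_prefix = paste0("ct", length(svs)))
          pieces[[ch]] <- splice_region(pieces[[ch]], ev$pieces)
          svs[[length(svs) + 1]] <- ev$svs
          if (n_states == 3 || stats::runif(1) < ct$bnd_prob) {
            other <- sample(setdiff(dict$chroms$chrom, ch), 1)
            svs[[length(svs) + 1]] <- data.frame(
              sv_id = sprintf("ctbnd_%s_%d", ch, length(svs)),
              chrom1 = ch,
              pos1 = round(stats::runif(1, r_start, r_start + region_len)),
              strand1 = sample(c("+", "-"), 1),
              chrom2 = other,
              pos2 = round(stats::runif(1, 1e6,
                                        chrom_length(dict, other) - 1e6)),
              strand2 = sample(c("+", "-"), 1),
              svclass = "BND", inserted_seq = NA_character_)
          }
          truth$chromothripsis <- rbind(truth$chromothripsis, data.frame(
            chrom = ch, start = r_start, end = r_start + region_len,
            n_breakpoints = n_bp, n_sv = nrow(ev$svs),
            n_states = n_states))
        }
      }
    })
  }

  # -- background SVs
  locus <- cfg$tp53_spec$locus
  with_seed(stage_seed("background_svs"), {
    rate <- if (cohort == "TP53_AML") cfg$sv_background$rate_tp53 else
      cfg$sv_background$rate_cbf
    n_bg <- stats::rpois(1, rate)
    bg <- make_background_svs(n_bg, cfg, dict, locus, prefix = "bg")
    if (nrow(bg)) svs[[length(svs) + 1]] <- bg
    if (cohort == "CBF_AML") {
      # recurrent translocation-like junction at two fixed loci
      svs[[length(svs) + 1]] <- data.frame(
        sv_id = "cbf_fusion", chrom1 = "chrT1",
        pos1 = round(35e6 + stats::runif(1, -5e4, 5e4)), strand1 = "+",
        chrom2 = "chrT2", pos2 = round(30e6 + stats::runif(1, -5e4, 5e4)),
        strand2 = "-", svclass = "BND", inserted_seq = NA_character_)
    }
  })
  sv_df <- if (length(svs)) do.call(rbind, svs) else NULL
  if (!is.null(sv_df)) {
    flip <- sv_df$chrom1 == sv_df$chrom2 & sv_df$pos1 > sv_df$pos2
    tmp <- sv_df$pos1[flip]
    sv_df$pos1[flip] <- sv_df$pos2[flip]
    sv_df$pos2[flip] <- tmp
    sv_df$sv_id <- make.unique(sv_df$sv_id)
  }

  # -- segments with log2 ratios
  seg <- do.call(rbind, lapply(names(pieces), function(ch) {
    p <- pieces[[ch]]
    data.frame(chrom = ch, start = p$start, end = p$end,
               total_cn = p$total, major_cn = p$major, minor_cn = p$minor)
  }))
  seg$log2_ratio <- with_seed(stage_seed("log2"), {
    log2((purity * seg$total_cn + 2 * (1 - purity)) / 2) +
      stats::rnorm(nrow(seg), 0, 0.02)
  })

  # -- heterozygous-site BAF
  baf <- with_seed(stage_seed("baf"), {
    do.call(rbind, lapply(names(pieces), function(ch) {
      len <- chrom_length(dict, ch)
      pos <- seq(cfg$baf_spacing / 2, len - 1, by = cfg$baf_spacing)
      p <- pieces[[ch]]
      idx <- findInterval(pos, p$start)
      tot <- p$total[idx]; maj <- p$major[idx]
      b_major <- (purity * maj + (1 - purity)) /
        (purity * tot + 2 * (1 - purity))
      is_major <- stats::runif(length(pos)) < 0.5
      b <- ifelse(is_major, b_major, 1 - b_major)
      data.frame(chrom = ch, pos = pos,
                 baf = stats::rbinom(length(pos), cfg$baf_depth, b) /
                   cfg$baf_depth,
                 depth = cfg$baf_depth)
    }))
  })

  # -- interstitial insertion loci
  ins <- cfg$insertion_spec
  ins_loci <- NULL
  germline_loci <- NULL
  with_seed(stage_seed("insertions"), {
    if (assign$ins_n > 0) {
      loci <- lapply(seq_len(assign$ins_n), function(k) {
        # anchor pool: intrachromosomal breakends far enough from the
        # chromosome ends that the planted locus cannot be pushed out of
        # the near-SV window by the termini mask
        bends <- if (!is.null(sv_df)) {
          intra <- sv_df[sv_df$chrom1 == sv_df$chrom2, , drop = FALSE]
          b <- rbind(data.frame(chrom = intra$chrom1, pos = intra$pos1),
                     data.frame(chrom = intra$chrom2, pos = intra$pos2))
          b[b$pos >= 6.2e5 &
              b$pos <= chrom_length(dict, b$chrom) - 6.2e5, , drop = FALSE]
        } else NULL
        use_sv <- !is.null(bends) && nrow(bends) > 0 && assign$ins_near[k]
        if (use_sv) {
          j <- sample(nrow(bends), 1)
          ch <- bends$chrom[j]
          pos <- bends$pos[j] + round(stats::runif(1, -ins$near_sv_max + 1,
                                                   ins$near_sv_max - 1))
        } else {
          ch <- sample(dict$chroms$chrom, 1,
                       prob = dict$chroms$length)
          pos <- round(stats::runif(1, 6e5,
                                    chrom_length(dict, ch) - 6e5))
        }
        pos <- min(max(pos, 6e5), chrom_length(dict, ch) - 6e5)
        data.frame(chrom = ch, pos = pos)
      })
      ins_loci <- do.call(rbind, loci)
      truth$insertions <- ins_loci
    }
    if (stats::runif(1) < ins$germline_prob) {
      ch <- sample(dict$chroms$chrom, 1, prob = dict$chroms$length)
      germline_loci <- data.frame(
        chrom = ch,
        pos = round(stats::runif(1, 6e5, chrom_length(dict, ch) - 6e5)))
    }
  })

  # -- reads
  tumor_reads <- normal_reads <- NULL
  tel <- cfg$telomere_spec
  if (cfg$emit_reads && tel$n_reads > 0) {
    shorten <- if (cohort == "TP53_AML") tel$shortening_tp53 else
      tel$shortening_cbf
    comp_tumor <- if (cohort == "TP53_AML") tel$tvr_tp53_tumor else
      tel$tvr_base
    tum <- with_seed(stage_seed("reads_tumor"), simulate_telomere_reads(
      tel$n_reads, tel$read_length, trpm = tel$normal_trpm - shorten,
      tvr_composition = comp_tumor,
      insertion_loci = rbind(ins_loci, germline_loci),
      insertion_support = ins$n_support, clip_len = ins$clip_len,
      aligned_len = ins$aligned_len, gc_probs = tel$gc_probs,
      frac_gc_matched = tel$frac_gc_matched, dict = dict,
      prefix = paste0(id, "_T")))
    nor <- with_seed(stage_seed("reads_normal"), simulate_telomere_reads(
      tel$n_reads, tel$read_length, trpm = tel$normal_trpm,
      tvr_composition = tel$tvr_base,
      insertion_loci = germline_loci,
      insertion_support = ins$n_support, clip_len = ins$clip_len,
      aligned_len = ins$aligned_len, gc_probs = tel$gc_probs,
      frac_gc_matched = tel$frac_gc_matched, dict = dict,
      prefix = paste0(id, "_N")))
    tumor_reads <- tum$reads
    normal_reads <- nor$reads
    truth$telomere <- list(tumor = tum$truth, normal = nor$truth)
  }

  profile <- sample_profile(
    sample_id = id, cohort_label = cohort, segments = seg,
    baf_sites = baf, svs = sv_df, small_variants = small_vars,
    purity = purity, ploidy = sum((seg$end - seg$start) * seg$total_cn) /
      sum(seg$end - seg$start),
    dict = dict)
  profile$tumor_reads <- tumor_reads
  profile$normal_reads <- normal_reads
  truth$sv_class_counts <- count_sv_classes(profile)
  list(profile = profile, truth = truth)
}

make_background_svs <- function(n, cfg, dict, avoid_locus, prefix) {
  if (n == 0) {
    return(data.frame(sv_id = character(), chrom1 = character(),
                      pos1 = numeric(), strand1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      strand2 = character(), svclass = character(),
                      inserted_seq = character()))
  }
  bg <- cfg$sv_background
  rows <- lapply(seq_len(n), function(k) {
    if (stats::runif(1) < bg$bnd_prob) {
      chs <- sample(dict$chroms$chrom, 2, prob = dict$chroms$length)
      data.frame(sv_id = sprintf("%s_%03d", prefix, k),
                 chrom1 = chs[1],
                 pos1 = safe_pos(chs[1], dict, avoid_locus),
                 strand1 = sample(c("+", "-"), 1),
                 chrom2 = chs[2],
                 pos2 = safe_pos(chs[2], dict, avoid_locus),
                 strand2 = sample(c("+", "-"), 1),
                 svclass = "BND", inserted_seq = NA_character_)
    } else {
      ch <- sample(dict$chroms$chrom, 1, prob = dict$chroms$length)
      size <- round(stats::runif(1, bg$size_range[1], bg$size_range[2]))
      p1 <- safe_pos(ch, dict, avoid_locus,
                     max_pos = chrom_length(dict, ch) - size - 1)
      if (stats::runif(1) < bg$ins_prob) {
        data.frame(sv_id = sprintf("%s_%03d", prefix, k), chrom1 = ch,
                   pos1 = p1, strand1 = "+", chrom2 = ch, pos2 = p1 + 1,
                   strand2 = "-", svclass = "INS",
                   inserted_seq = paste(sample(c("A", "C", "G", "T"), 50,
                                               replace = TRUE),
                                        collapse = ""))
      } else {
        oi <- sample(3, 1)
        orient <- list(c("+", "-"), c("-", "+"), c("+", "+"))[[oi]]
        data.frame(sv_id = sprintf("%s_%03d", prefix, k), chrom1 = ch,
                   pos1 = p1, strand1 = orient[1], chrom2 = ch,
                   pos2 = p1 + size, strand2 = orient[2],
                   svclass = c("DEL", "DUP", "INV")[oi],
                   inserted_seq = NA_character_)
      }
    }
  })
  do.call(rbind, rows)
}

# uniform position avoiding the classification locus (so background SVs
# never fake a TP53 disruption)
safe_pos <- function(ch, dict, locus, max_pos = NULL) {
  if (is.null(max_pos)) max_pos <- chrom_length(dict, ch) - 1
  for (i in 1:50) {
    p <- round(stats::runif(1, 1e4, max_pos))
    if (ch != locus$chrom || p < locus$start - 1e4 || p > locus$end + 1e4) {
      return(p)
    }
  }
  locus$end + 2e4
}

write_cohort <- function(profiles, truth, out_dir, dict) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(profiles, function(p) {
    d <- file.path(out_dir, p$sample_id)
    dir.create(d, showWarnings = FALSE)
    write_segments(p$segments, file.path(d, "segments.tsv"))
    write_baf(p$baf_sites, file.path(d, "baf.tsv"))
    write_bedpe(p$svs, file.path(d, "svs.bedpe"))
    write_vcf(p$small_variants, file.path(d, "small_variants.vcf"), dict)
    has_reads <- !is.null(p$tumor_reads)
    if (has_reads) {
      write_sam(p$tumor_reads, file.path(d, "tumor.sam"), dict)
      write_sam(p$normal_reads, file.path(d, "normal.sam"), dict)
    }
    data.frame(sample_id = p$sample_id, cohort_label = p$cohort_label,
               purity = p$purity, ploidy = p$ploidy,
               segments = file.path(p$sample_id, "segments.tsv"),
               baf = file.path(p$sample_id, "baf.tsv"),
               svs = file.path(p$sample_id, "svs.bedpe"),
               small_variants = file.path(p$sample_id,
                                          "small_variants.vcf"),
               tumor_reads = if (has_reads) {
                 file.path(p$sample_id, "tumor.sam")
               } else NA_character_,
               normal_reads = if (has_reads) {
                 file.path(p$sample_id, "normal.sam")
               } else NA_character_)
  })
  sheet <- do.call(rbind, rows)
  utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
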