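small_tel_spec <- list(
  read_length = 102, n_reads = 400, normal_trpm = 3000,
  shortening_tp53 = 2.5, shortening_cbf = 226,
  tvr_base = c(TTTGGG = 0.005), tvr_tp53_tumor = c(TTTGGG = 0.02),
  gc_probs = c(0.40, 0.50), frac_gc_matched = 0.35)

test_that("identical seed and config give byte-identical cohorts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 23, n_tp53 = 3, n_cbf = 1,
                    telomere_spec = small_tel_spec)
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 10)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("per-sample streams are stable when the cohort grows", {
  # event types are assigned as a cohort-level composition, but all
  # within-sample draws come from per-(sample, stage) streams: adding
  # comparator samples leaves every TP53 sample untouched, and growing
  # the TP53 arm leaves per-sample noise stages (purity) untouched
  cfg_a <- sim_config(seed = 23, n_tp53 = 4, n_cbf = 0, emit_reads = FALSE)
  cfg_b <- sim_config(seed = 23, n_tp53 = 4, n_cbf = 3, emit_reads = FALSE)
  sa <- simulate_cohort(cfg_a)
  sb <- simulate_cohort(cfg_b)
  for (id in names(sa$profiles)) {
    expect_equal(sa$profiles[[id]]$segments, sb$profiles[[id]]$segments)
    expect_equal(sa$profiles[[id]]$svs, sb$profiles[[id]]$svs)
  }
  cfg_c <- sim_config(seed = 23, n_tp53 = 6, n_cbf = 0, emit_reads = FALSE)
  sc <- simulate_cohort(cfg_c)
  expect_equal(sa$profiles[["TP53_003"]]$purity,
               sc$profiles[["TP53_003"]]$purity)
})

test_that("empty cohorts and full-prevalence chromothripsis behave as configured", {
  s0 <- simulate_cohort(sim_config(seed = 1, n_tp53 = 0, n_cbf = 0))
  expect_length(s0$profiles, 0)
  expect_length(s0$truth$samples, 0)

  ct <- sim_config(seed = 29, n_tp53 = 10, n_cbf = 0,
                   emit_reads = FALSE)$chromothripsis_spec
  ct$prob <- 1
  sim <- simulate_cohort(sim_config(seed = 29, n_tp53 = 10, n_cbf = 0,
                                    emit_reads = FALSE,
                                    chromothripsis_spec = ct))
  n_regions <- vapply(sim$truth$samples,
                      function(t) nrow(t$chromothripsis), integer(1))
  expect_true(all(n_regions >= 1))
})

test_that("a chromothripsis event cuts k breakpoints into k+1 fragments", {
  set.seed(211)
  ev <- simulate_chromothripsis_event("chrT1", 20e6, 30e6, 10,
                                      min_seg = 1e3)
  expect_equal(nrow(ev$pieces), 11)
  expect_equal(min(ev$pieces$start), 20e6)
  expect_equal(max(ev$pieces$end), 30e6)
  # two-state events alternate strictly: every segment oscillates
  cn <- ev$pieces$total
  expect_true(all(diff(cn) != 0))
  expect_equal(sort(unique(cn)), c(1, 2))
  expect_equal(oscillation_run(data.frame(total_cn = cn))$run_length,
               length(cn))
  # too many breakpoints for the region errors
  expect_error(simulate_chromothripsis_event("chrT1", 0, 1e4, 20,
                                             min_seg = 1e3),
               "too short")
  expect_error(simulate_chromothripsis_event("chrT1", 0, 1e6, 4),
               "at least 6")
})

test_that("join orientations are uniform over the four classes", {
  set.seed(221)
  counts <- c(del_like = 0, dup_like = 0, inv_h2h = 0, inv_t2t = 0)
  reps <- 700  # 700 events x ~15 joins ~ 10,000 draws
  for (i in seq_len(reps)) {
    ev <- simulate_chromothripsis_event("chrT1", 10e6, 40e6, 30,
                                        min_seg = 1e3)
    cls <- ifelse(ev$svs$strand1 == "+" & ev$svs$strand2 == "-", 1,
           ifelse(ev$svs$strand1 == "-" & ev$svs$strand2 == "+", 2,
           ifelse(ev$svs$strand1 == "+" & ev$svs$strand2 == "+", 3, 4)))
    counts <- counts + tabulate(cls, nbins = 4)
  }
  gof <- suppressWarnings(chisq.test(counts, p = rep(0.25, 4)))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulated CN-LOH shows the purity-scaled BAF shift at neutral log2", {
  arm <- arm_interval(tdict, "chrT3p")
  set.seed(231)
  r1 <- simulate_cnloh(arm, purity = 1)
  expect_equal(r1$segments$total_cn, 2)
  expect_equal(r1$segments$minor_cn, 0)
  folded1 <- pmax(r1$baf_sites$baf, 1 - r1$baf_sites$baf)
  expect_equal(mean(folded1), 1.0, tolerance = 0.01)

  r5 <- simulate_cnloh(arm, purity = 0.5)
  folded5 <- pmax(r5$baf_sites$baf, 1 - r5$baf_sites$baf)
  # (1 + 0.5)/2 = 0.75, plus a small upward folding bias at depth 40
  expect_equal(mean(folded5), 0.75, tolerance = 0.02)

  r0 <- simulate_cnloh(arm, purity = 1e-6)
  expect_equal(mean(r0$baf_sites$baf), 0.5, tolerance = 0.02)
})

test_that("every planted event is present in the emitted files (direct scan)", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 37, n_tp53 = 6, n_cbf = 0,
                    telomere_spec = small_tel_spec)
  sim <- simulate_cohort(cfg, out_dir = dir)
  for (i in seq_along(sim$profiles)) {
    tr <- sim$truth$samples[[i]]
    d <- file.path(dir, tr$sample_id)
    seg <- utils::read.table(file.path(d, "segments.tsv"), header = TRUE)
    vcf_lines <- readLines(file.path(d, "small_variants.vcf"))
    sam <- readLines(file.path(d, "tumor.sam"))

    # arm events appear as non-diploid segments at arm positions not
    # locally overwritten by a planted chromothripsis region
    for (k in seq_len(nrow(tr$arm_events))) {
      arm <- arm_interval(tdict, tr$arm_events$arm[k])
      cands <- arm$start + c(0.5, 0.25, 0.75, 0.1, 0.9) *
        (arm$end - arm$start)
      ct <- tr$chromothripsis
      free <- cands[vapply(cands, function(x) {
        !any(ct$chrom == arm$chrom & x >= ct$start & x < ct$end)
      }, logical(1))]
      if (!length(free)) next
      pt <- free[1]
      s <- seg[seg$chrom == arm$chrom & seg$start <= pt & seg$end > pt, ]
      if (tr$arm_events$type[k] == "loss") {
        expect_equal(s$total_cn, 1)
      } else {
        expect_equal(s$total_cn, 3)
      }
    }
    # TP53 SNVs appear in the VCF body
    if (tr$tp53$mechanism != "wild_type") {
      expect_true(any(grepl("GENE=TP53", vcf_lines)))
    }
    # chromothripsis regions contain oscillating segments
    for (k in seq_len(nrow(tr$chromothripsis))) {
      reg <- tr$chromothripsis[k, ]
      inside <- seg[seg$chrom == reg$chrom & seg$start >= reg$start &
                      seg$end <= reg$end, ]
      expect_gte(nrow(inside), reg$n_breakpoints - 1)
      expect_true(all(diff(round_half_up(inside$total_cn)) != 0))
    }
    # planted insertion loci have clipped reads in the tumour SAM
    for (k in seq_len(nrow(tr$insertions))) {
      pat <- sprintf("\t%s\t%d\t", tr$insertions$chrom[k],
                     tr$insertions$pos[k] - 54 + 1)
      expect_true(any(grepl(pat, sam, fixed = TRUE)))
    }
  }
})

test_that("arm-loss frequencies match the aneuploidy spec within 3 SE", {
  ct_off <- list(prob = 0, second_event_prob = 0, bp_range = c(24, 40),
                 massive_prob = 0, massive_bp_range = c(50, 60),
                 chrom_weights = c(chrT1 = 1), allowed_arms = list(chrT1 = "q"),
                 region_mb = 8, min_seg = 1e3, third_state_prob = 0,
                 bnd_prob = 0)
  n <- 1000
  cfg <- sim_config(seed = 41, n_tp53 = n, n_cbf = 0, baf_spacing = 5e6,
                    emit_reads = FALSE, chromothripsis_spec = ct_off)
  sim <- simulate_cohort(cfg)
  for (k in seq_len(nrow(cfg$aneuploidy_spec))) {
    p_true <- cfg$aneuploidy_spec$loss_prob[k]
    if (p_true == 0) next
    hit <- mean(vapply(sim$truth$samples, function(t) {
      any(t$arm_events$arm == cfg$aneuploidy_spec$arm[k] &
            t$arm_events$type == "loss")
    }, logical(1)))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(hit - p_true), 3 * se + 1e-9)
  }
})
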