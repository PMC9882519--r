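two_state_profile <- function(frac_cn2, cn_other = 1, major_other = 1,
                              minor_other = 0) {
  # chrT1 split so that frac_cn2 of the whole toy genome is CN 2
  total_len <- sum(tdict$chroms$length)
  cn2_len <- frac_cn2 * total_len
  seg <- list()
  remaining <- cn2_len
  for (i in seq_len(nrow(tdict$chroms))) {
    ch <- tdict$chroms$chrom[i]
    len <- tdict$chroms$length[i]
    take <- min(len, remaining)
    if (take > 0) {
      seg[[length(seg) + 1]] <- seg_row(ch, 0, take, 2, 1, 1)
    }
    if (take < len) {
      seg[[length(seg) + 1]] <- seg_row(ch, take, len, cn_other,
                                        major_other, minor_other)
    }
    remaining <- remaining - take
  }
  make_profile(segments = do.call(rbind, seg))
}

test_that("mostly-diploid filter follows the 50% copy-neutral rule", {
  expect_true(is_mostly_diploid(two_state_profile(0.60)))
  expect_false(is_mostly_diploid(two_state_profile(0.40)))
  # tetraploid genome is excluded through the WGD rule
  tetra <- make_profile(segments = transform(diploid_segments(),
                                             total_cn = 4, major_cn = 2,
                                             minor_cn = 2, log2_ratio = 1))
  expect_false(is_mostly_diploid(tetra))
  expect_true(detect_wgd(tetra))
  expect_false(detect_wgd(make_profile()))
})

test_that("WGD detection equals a base-weighted brute-force fraction", {
  set.seed(113)
  for (rep in 1:10) {
    seg <- do.call(rbind, lapply(tdict$chroms$chrom, function(ch) {
      len <- chrom_length(tdict, ch)
      cuts <- sort(sample(seq(1e6, len - 1e6, by = 1e6),
                          sample(2:5, 1)))
      bounds <- c(0, cuts, len)
      do.call(rbind, lapply(seq_len(length(bounds) - 1), function(i) {
        major <- sample(1:3, 1); minor <- sample(0:min(major, 2), 1)
        seg_row(ch, bounds[i], bounds[i + 1], major + minor, major, minor)
      }))
    }))
    p <- make_profile(segments = seg)
    frac <- sum((seg$end - seg$start)[round_half_up(seg$major_cn) >= 2]) /
      sum(seg$end - seg$start)
    expect_equal(detect_wgd(p), frac > 0.5)
  }
})

test_that("landscape fractions count each sample once per unit", {
  units <- data.frame(chrom = "chrT1", start = 5e6, end = 6e6,
                      gene = "U1")
  lossy <- make_profile(segments = rbind(
    seg_row("chrT1", 0, 20e6, 1, 1, 0),
    seg_row("chrT1", 20e6, 50e6, 2, 1, 1),
    diploid_segments()[-1, ]))
  cohort <- list(lossy, lossy, make_profile("S3"), make_profile("S4"))
  ls <- cn_frequency_landscape(cohort, units)
  expect_equal(ls$loss_fraction, 0.5)
  expect_equal(ls$gain_fraction, 0)
  # all-diploid cohort gives all-zero fractions
  ls0 <- cn_frequency_landscape(list(make_profile(), make_profile()), units)
  expect_equal(ls0$loss_fraction + ls0$gain_fraction, 0)
  expect_error(cn_frequency_landscape(list(), units), "empty")
})

test_that("landscape is invariant to segment re-splitting and filter idempotent", {
  units <- data.frame(chrom = "chrT2", start = 30e6, end = 31e6)
  seg <- diploid_segments()
  p <- make_profile(segments = seg)
  split_seg <- rbind(
    transform(seg[seg$chrom == "chrT2", ], end = 20e6),
    transform(seg[seg$chrom == "chrT2", ], start = 20e6),
    seg[seg$chrom != "chrT2", ])
  p_split <- make_profile(segments = split_seg)
  expect_equal(cn_frequency_landscape(list(p), units)$loss_fraction,
               cn_frequency_landscape(list(p_split), units)$loss_fraction)
  cohort <- list(p, p_split)
  once <- Filter(is_mostly_diploid, cohort)
  twice <- Filter(is_mostly_diploid, once)
  expect_equal(length(once), length(twice))
})

test_that("minimally deleted region is the common interval of the losses", {
  mk_loss <- function(id, s, e) {
    make_profile(id, segments = rbind(
      seg_row("chrT4", s, e, 1, 1, 0),
      if (s > 0) seg_row("chrT4", 0, s, 2, 1, 1),
      if (e < 10e6) seg_row("chrT4", e, 10e6, 2, 1, 1),
      diploid_segments()[tdict$chroms$chrom != "chrT4" &
                           diploid_segments()$chrom != "chrT4", ]))
  }
  cohort <- list(mk_loss("A", 1.0e6, 2.0e6), mk_loss("B", 1.5e6, 3.0e6),
                 mk_loss("C", 1.2e6, 2.5e6))
  mdr <- minimal_deleted_region(cohort, "chrT4p")
  expect_equal(mdr$interval$start, 1.5e6)
  expect_equal(mdr$interval$end, 2.0e6)
  expect_equal(mdr$n_supporting_samples, 3)
  expect_true(mdr$universal)
  # containment invariant
  for (ir in mdr$per_sample_losses) {
    expect_true(any(IRanges::start(ir) - 1 <= mdr$interval$start &
                      IRanges::end(ir) >= mdr$interval$end))
  }
  # single-sample arm: the MDR is that sample's loss
  single <- minimal_deleted_region(list(mk_loss("A", 0.5e6, 1.0e6)),
                                   "chrT4p")
  expect_equal(single$interval$start, 0.5e6)
  expect_equal(single$interval$end, 1.0e6)
  # disjoint losses: deepest interval flagged non-universal
  disj <- minimal_deleted_region(
    list(mk_loss("A", 0.5e6, 1.0e6), mk_loss("B", 0.6e6, 1.1e6),
         mk_loss("C", 2.0e6, 2.5e6)), "chrT4p")
  expect_false(disj$universal)
  expect_equal(disj$n_supporting_samples, 2)
})

test_that("planted deletion core is recovered exactly with its gene content", {
  cfg <- sim_config(seed = 5, n_tp53 = 42, n_cbf = 0, emit_reads = FALSE)
  sim <- simulate_cohort(cfg)
  mdr <- minimal_deleted_region(sim$profiles, "chrT4p",
                                annotation = toy_gene_annotation())
  core <- sim$truth$mdr_core
  expect_equal(mdr$interval$start, core$start)
  expect_equal(mdr$interval$end, core$end)
  expect_equal(mdr$interval$end - mdr$interval$start, 2.75e6)
  expect_equal(length(mdr$gene_symbols_contained), 18)
  expect_true(all(c("ETV6", "CDKN1B") %in% mdr$gene_symbols_contained))
  n_losses <- sum(vapply(sim$truth$samples,
                         function(t) !is.null(t$mdr_loss), logical(1)))
  expect_equal(mdr$n_supporting_samples, n_losses)
})

test_that("landscape comparison flags planted contrasts and only those", {
  units <- data.frame(chrom = c("chrT1", "chrT2"), start = c(5e6, 5e6),
                      end = c(6e6, 6e6), gene = c("U1", "U2"))
  lossy <- make_profile(segments = rbind(
    seg_row("chrT1", 0, 20e6, 1, 1, 0),
    seg_row("chrT1", 20e6, 50e6, 2, 1, 1),
    diploid_segments()[-1, ]))
  a <- cn_frequency_landscape(rep(list(lossy), 6), units)
  b <- cn_frequency_landscape(rep(list(make_profile()), 6), units)
  cmp <- compare_landscapes(a, b)
  expect_equal(cmp$delta_loss[cmp$gene == "U1"], 1)
  expect_equal(cmp$delta_loss[cmp$gene == "U2"], 0)
  expect_lt(cmp$p[cmp$gene == "U1"], 0.05)
  same <- compare_landscapes(a, a)
  expect_true(all(same$delta_loss == 0))
  expect_true(all(same$p == 1))
})

test_that("simulated arm-loss landscape matches the generating rates", {
  # segment-level cohort at scale: reads off, chromothripsis off,
  # sparse BAF so the draw is dominated by the aneuploidy spec
  ct_off <- list(prob = 0, second_event_prob = 0, bp_range = c(24, 40),
                 massive_prob = 0, massive_bp_range = c(50, 60),
                 chrom_weights = c(chrT1 = 1), allowed_arms = list(chrT1 = "q"),
                 region_mb = 8, min_seg = 1e3, third_state_prob = 0,
                 bnd_prob = 0)
  cfg <- sim_config(seed = 17, n_tp53 = 400, n_cbf = 0,
                    baf_spacing = 5e6, emit_reads = FALSE,
                    chromothripsis_spec = ct_off)
  sim <- simulate_cohort(cfg)
  arms <- cfg$aneuploidy_spec
  for (k in seq_len(nrow(arms))) {
    if (arms$loss_prob[k] == 0) next
    hit <- mean(vapply(sim$truth$samples, function(t) {
      any(t$arm_events$arm == arms$arm[k] & t$arm_events$type == "loss")
    }, logical(1)))
    se <- sqrt(arms$loss_prob[k] * (1 - arms$loss_prob[k]) / 400)
    expect_lt(abs(hit - arms$loss_prob[k]), 3 * se + 1e-9)
    # and the emitted segments carry the event: landscape over the arm
    arm <- arm_interval(tdict, arms$arm[k])
    unit <- data.frame(chrom = arm$chrom,
                       start = (arm$start + arm$end) / 2 - 5e5,
                       end = (arm$start + arm$end) / 2 + 5e5)
    ls <- cn_frequency_landscape(sim$profiles, unit)
    expect_lt(abs(ls$loss_fraction - hit), 0.02 + 1e-9)
  }
})
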