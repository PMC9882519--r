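cnloh_fixture <- function(baf_values, l2 = 0, chrom = "chrT3",
                          spacing = 4e4) {
  pos <- seq(2e4, by = spacing, length.out = length(baf_values))
  baf <- data.frame(chrom = chrom, pos = pos, baf = baf_values, depth = 40)
  seg <- rbind(seg_row(chrom, 0, 2.5e7, 2, 1, 1, l2))
  list(seg = seg, baf = baf)
}

test_that("pure-tumour LOH over an arm is detected as one region", {
  set.seed(121)
  fx <- cnloh_fixture(runif(250, 0.98, 1.0))
  r <- detect_cnloh(fx$seg, fx$baf, purity = 1)
  expect_equal(nrow(r), 1)
  expect_gte(r$mean_major_baf, 0.95)
  expect_equal(r$n_sites, 250)
  # balanced heterozygosity yields nothing
  fx0 <- cnloh_fixture(rep(0.5, 250))
  expect_equal(nrow(detect_cnloh(fx0$seg, fx0$baf, purity = 1)), 0)
})

test_that("detection threshold follows 0.5 + rho/2 - tau exactly", {
  th <- allele_status_thresholds()
  th$tau_baf <- 0.03
  # at purity 0.5 the cutoff is 0.72: folded mean 0.75 detected
  fx_hi <- cnloh_fixture(rep(0.75, 100))
  expect_equal(nrow(detect_cnloh(fx_hi$seg, fx_hi$baf, 0.5, th)), 1)
  # folded mean 0.70 < 0.72 is not
  fx_lo <- cnloh_fixture(rep(0.70, 100))
  expect_equal(nrow(detect_cnloh(fx_lo$seg, fx_lo$baf, 0.5, th)), 0)
  # and a non-neutral log2 ratio vetoes the call
  fx_cn <- cnloh_fixture(rep(0.75, 100), l2 = -0.5)
  expect_equal(nrow(detect_cnloh(fx_cn$seg, fx_cn$baf, 0.5, th)), 0)
})

test_that("detect_cnloh equals the brute-force maximal-window scan", {
  brute <- function(seg, baf, purity, th) {
    baf <- baf[order(baf$pos), ]
    seg_idx <- findInterval(baf$pos, seg$start)
    keep <- seg_idx >= 1 & baf$pos < seg$end[pmax(seg_idx, 1)]
    baf <- baf[keep, ]
    l2 <- seg$log2_ratio[seg_idx[keep]]
    folded <- pmax(baf$baf, 1 - baf$baf)
    n <- nrow(baf)
    thr <- 0.5 + purity / 2 - th$tau_baf
    sat <- list()
    for (i in seq_len(n)) for (j in i:n) {
      if (j - i + 1 < th$n_min) next
      if (mean(folded[i:j]) >= thr - 1e-12 &&
          abs(mean(l2[i:j])) <= th$tau_cn + 1e-12) {
        sat[[length(sat) + 1]] <- c(i, j)
      }
    }
    if (!length(sat)) return(data.frame(start = numeric(),
                                        end = numeric()))
    sat <- do.call(rbind, sat)
    maximal <- vapply(seq_len(nrow(sat)), function(k) {
      !any(sat[, 1] <= sat[k, 1] & sat[, 2] >= sat[k, 2] &
             (sat[, 1] != sat[k, 1] | sat[, 2] != sat[k, 2]))
    }, logical(1))
    sat <- sat[maximal, , drop = FALSE]
    data.frame(start = baf$pos[sat[, 1]], end = baf$pos[sat[, 2]] + 1)
  }
  th <- allele_status_thresholds()
  th$n_min <- 5
  set.seed(131)
  for (rep in 1:6) {
    n <- sample(30:80, 1)
    state <- rep(0.5, n)
    # plant 0-2 shifted stretches
    for (k in seq_len(sample(0:2, 1))) {
      i <- sample(n - 10, 1)
      state[i:(i + sample(5:10, 1))] <- 0.85
    }
    vals <- pmin(1, pmax(0, state + rnorm(n, 0, 0.03)))
    fx <- cnloh_fixture(vals)
    mine <- detect_cnloh(fx$seg, fx$baf, 0.7, th)
    oracle <- brute(fx$seg, fx$baf, 0.7, th)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
    }
  }
})

test_that("locus classification combines SNVs with CN evidence", {
  locus <- tp53_locus_toy()
  snv <- data.frame(chrom = "chrT3", pos = 7.01e6, ref = "C", alt = "T",
                    vaf = 0.489, gene = "TP53", effect = "missense")
  # SNV at 48.9% VAF plus CN-LOH over the locus: multi-hit
  set.seed(141)
  fx <- cnloh_fixture(rbinom(250, 40, 0.95) / 40)
  seg <- rbind(seg_row("chrT3", 0, 1e7, 2, 2, 0, 0),
               seg_row("chrT3", 1e7, 2.5e7, 2, 1, 1, 0),
               diploid_segments()[diploid_segments()$chrom != "chrT3", ])
  p <- make_profile(segments = seg, baf = fx$baf, small = snv, purity = 0.9)
  call <- classify_locus(locus, p)
  expect_equal(call$category, "MULTI_HIT")
  expect_true(all(c("SNV", "CN_LOH") %in% call$mechanisms))
  expect_equal(call$biallelic, "BIALLELIC")

  # one SNV on a balanced diploid locus: monoallelic
  p2 <- make_profile(small = snv, purity = 0.9)
  call2 <- classify_locus(locus, p2)
  expect_equal(call2$category, "MONOALLELIC")
  expect_equal(call2$biallelic, "NOT_APPLICABLE")

  # no hits at all: wild-type
  call3 <- classify_locus(locus, make_profile())
  expect_equal(call3$category, "WILD_TYPE")
  expect_equal(call3$biallelic, "NOT_APPLICABLE")
})

test_that("copy loss requires an absent minor allele, not a subclonal dip", {
  locus <- tp53_locus_toy()
  snv <- data.frame(chrom = "chrT3", pos = 7.01e6, ref = "C", alt = "T",
                    vaf = 0.3, gene = "TP53", effect = "missense")
  dip <- rbind(seg_row("chrT3", 0, 1e7, 1.6, 1, 0.6, -0.3),
               seg_row("chrT3", 1e7, 2.5e7, 2, 1, 1, 0),
               diploid_segments()[diploid_segments()$chrom != "chrT3", ])
  p <- make_profile(segments = dip, small = snv)
  call <- classify_locus(locus, p)
  expect_false("CN_LOSS" %in% call$mechanisms)
  expect_equal(call$category, "MONOALLELIC")
})

test_that("two-SNV biallelic resolution follows the copy-fraction rule", {
  locus <- tp53_locus_toy()
  mk2 <- function(v1, v2, purity) {
    small <- data.frame(chrom = "chrT3", pos = c(7.005e6, 7.015e6),
                        ref = c("C", "G"), alt = c("T", "A"),
                        vaf = c(v1, v2), gene = "TP53",
                        effect = "missense")
    make_profile(small = small, purity = purity)
  }
  # f = vaf * (rho*CN + 2(1-rho)) / (rho*CN); CN = 2
  # vaf .30/.25 at rho .6: f = .5 + .4167 <= 1 -> unresolved
  c1 <- classify_locus(locus, mk2(0.30, 0.25, 0.6))
  expect_equal(c1$category, "MULTI_HIT")
  expect_equal(c1$biallelic, "UNRESOLVED")
  # vaf .48/.45 at rho .9: f = .533 + .5 > 1 -> biallelic
  c2 <- classify_locus(locus, mk2(0.48, 0.45, 0.9))
  expect_equal(c2$biallelic, "BIALLELIC")
  # trans phasing, when annotated, resolves directly
  p3 <- mk2(0.30, 0.25, 0.6)
  p3$small_variants$phase <- c("trans", "trans")
  expect_equal(classify_locus(locus, p3)$biallelic, "BIALLELIC")
  # contract: resolving a non-multi-hit call is an error
  mono <- classify_locus(locus, make_profile())
  expect_error(resolve_biallelic(mono, make_profile()), "MULTI_HIT")
})

test_that("adding hit mechanisms never demotes the category", {
  locus <- tp53_locus_toy()
  rank <- c(WILD_TYPE = 0, MONOALLELIC = 1, MULTI_HIT = 2)
  snv <- data.frame(chrom = "chrT3", pos = 7.01e6, ref = "C", alt = "T",
                    vaf = 0.45, gene = "TP53", effect = "missense")
  loss_seg <- rbind(seg_row("chrT3", 0, 1e7, 1, 1, 0),
                    seg_row("chrT3", 1e7, 2.5e7, 2, 1, 1, 0),
                    diploid_segments()[diploid_segments()$chrom != "chrT3", ])
  disrupt <- make_sv("d", "chrT3", 7.01e6, "+", "chrT3", 9e6, "-")
  profiles <- list(
    make_profile(),
    make_profile(small = snv),
    make_profile(small = snv, segments = loss_seg),
    make_profile(small = snv, segments = loss_seg, svs = disrupt))
  cats <- vapply(profiles, function(p)
    classify_locus(locus, p)$category, "")
  expect_true(all(diff(rank[cats]) >= 0))
})

test_that("planted mechanism mixes are recovered at 99% or better", {
  cfg <- sim_config(seed = 19, n_tp53 = 60, n_cbf = 10, emit_reads = FALSE)
  sim <- simulate_cohort(cfg)
  m <- recovery_metrics(sim)
  expect_gte(m$tp53_category_recovery, 0.99)
})
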