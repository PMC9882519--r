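#' @title Cohort copy-number landscapes
#'
#' @description
#' Sample filtering (mostly-diploid, whole-genome doubling), gene- or
#' bin-level gain/loss frequency landscapes, cross-cohort comparison,
#' and minimally-deleted regions. "Copy neutral" means rounded total
#' copy number 2 on autosomes; sex chromosomes are excluded throughout.
#' @name cn_cohort
NULL

# base-weighted fraction of covered autosomal bases satisfying pred(seg)
autosome_fraction <- function(profile, pred) {
  seg <- profile$segments
  auto <- profile$dict$chroms$chrom[profile$dict$chroms$autosome]
  seg <- seg[seg$chrom %in% auto, , drop = FALSE]
  covered <- sum(seg$end - seg$start)
  check_that(covered > 0, "sample %s has zero autosomal segment coverage",
             profile$sample_id)
  sum((seg$end - seg$start)[pred(seg)]) / covered
}

#' Whole-genome doubling detection
#'
#' A genome is called doubled when more than half of its covered
#' autosomal bases have major allele copy number of at least 2
#' (rounded). The published landscape figure excludes doubled genomes
#' but does not print its rule; this base-weighted majority rule is the
#' package's own and is threshold-configurable.
#'
#' @param profile a [sample_profile()].
#' @param threshold fraction of bases with `major_cn >= 2` above which
#'   WGD is called.
#' @return logical.
#' @export
detect_wgd <- function(profile, threshold = 0.5) {
  frac <- autosome_fraction(profile, function(s)
    round_half_up(s$major_cn) >= 2)
  frac > threshold
}

#' Mostly-diploid sample filter
#'
#' TRUE when at least `min_neutral` of covered autosomal bases are copy
#' neutral (rounded total copy number exactly 2) and the genome shows no
#' whole-genome doubling. Segment gaps are treated as unknown and
#' excluded from the denominator.
#'
#' @inheritParams detect_wgd
#' @param min_neutral minimum copy-neutral base fraction (default 0.5).
#' @return logical.
#' @export
is_mostly_diploid <- function(profile, min_neutral = 0.5) {
  frac <- autosome_fraction(profile, function(s)
    round_half_up(s$total_cn) == 2)
  frac >= min_neutral && !detect_wgd(profile)
}

# majority-overlap CN state of one unit for one sample:
# "loss" if >50% of unit bases rounded CN < 2, "gain" if > 2, else neutral
unit_state <- function(seg, chrom, start, end) {
  s <- seg[seg$chrom == chrom & seg$end > start & seg$start < end, ,
           drop = FALSE]
  if (!nrow(s)) return("neutral")
  w <- pmin(s$end, end) - pmax(s$start, start)
  cn <- round_half_up(s$total_cn)
  width <- end - start
  loss <- sum(w[cn < 2]) / width
  gain <- sum(w[cn > 2]) / width
  if (loss > 0.5) "loss" else if (gain > 0.5) "gain" else "neutral"
}

#' Gene/bin-level gain-loss frequency landscape
#'
#' For each unit (gene body or fixed bin), a sample counts as "loss"
#' when the majority (> 50%) of the unit's bases have rounded total
#' copy number below 2, as "gain" when above 2 (ties break toward
#' neutral), and once only -- so `gain_fraction + loss_fraction <= 1`
#' per unit. The cohort should be pre-filtered with
#' [is_mostly_diploid()].
#'
#' @param profiles list of [sample_profile()] objects (already
#'   filtered).
#' @param units data.frame `chrom, start, end` plus optional `gene`.
#' @return data.frame `chrom, start, end, gene, gain_fraction,
#'   loss_fraction, n_samples_included`.
#' @export
cn_frequency_landscape <- function(profiles, units) {
  check_that(length(profiles) > 0, "empty (filtered) cohort")
  if (is.null(units$gene)) units$gene <- NA_character_
  n <- length(profiles)
  states <- vapply(seq_len(nrow(units)), function(i) {
    st <- vapply(profiles, function(p)
      unit_state(p$segments, units$chrom[i], units$start[i], units$end[i]),
      character(1))
    c(gain = sum(st == "gain") / n, loss = sum(st == "loss") / n)
  }, numeric(2))
  data.frame(chrom = units$chrom, start = units$start, end = units$end,
             gene = units$gene,
             gain_fraction = states["gain", ],
             loss_fraction = states["loss", ],
             n_samples_included = n)
}

#' Minimally-deleted region of a chromosome arm
#'
#' The maximal interval contained in the deletion footprint of every
#' supporting sample. Per sample, the loss footprint is the union of
#' its segments with rounded total copy number below 2 on the arm;
#' supporting samples are those whose footprint intersects the shared
#' core. Computed as the deepest interval of the per-sample loss
#' coverage: when some losses on the arm do not share a common
#' interval, the region supported by the largest number of samples is
#' returned and flagged non-universal.
#'
#' @param profiles list of [sample_profile()] objects.
#' @param arm_name arm such as `"chrT4p"`.
#' @param annotation optional gene table (`chrom, start, end, gene`);
#'   genes whose bodies lie fully inside the region are reported.
#' @param dict reference dictionary (defaults to the first profile's).
#' @return list with `interval` (`chrom, start, end`),
#'   `n_supporting_samples`, `universal` (TRUE when every sample with a
#'   loss on the arm supports the region), `gene_symbols_contained`,
#'   and `per_sample_losses`.
#' @export
minimal_deleted_region <- function(profiles, arm_name, annotation = NULL,
                                   dict = NULL) {
  if (is.null(dict)) dict <- profiles[[1]]$dict
  arm <- arm_interval(dict, arm_name)
  losses <- list()
  for (p in profiles) {
    seg <- p$segments
    s <- seg[seg$chrom == arm$chrom & seg$end > arm$start &
               seg$start < arm$end &
               round_half_up(seg$total_cn) < 2, , drop = FALSE]
    if (!nrow(s)) next
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(s$start, arm$start) + 1,
      end = pmin(s$end, arm$end)))
    losses[[p$sample_id]] <- ir
  }
  check_that(length(losses) >= 1, "no sample has a loss on %s", arm_name)
  cov <- Reduce(`+`, lapply(losses, function(ir)
    IRanges::coverage(ir, width = arm$end)))
  depth <- max(S4Vectors::runValue(cov))
  deepest <- IRanges::slice(cov, lower = depth, rangesOnly = TRUE)
  widest <- deepest[which.max(IRanges::width(deepest))]
  interval <- list(chrom = arm$chrom,
                   start = IRanges::start(widest) - 1,
                   end = IRanges::end(widest))
  genes <- character(0)
  if (!is.null(annotation)) {
    g <- annotation[annotation$chrom == interval$chrom &
                      annotation$start >= interval$start &
                      annotation$end <= interval$end, , drop = FALSE]
    genes <- g$gene
  }
  list(interval = interval,
       n_supporting_samples = depth,
       universal = depth == length(losses),
       gene_symbols_contained = genes,
       per_sample_losses = losses)
}

#' Compare two cohort landscapes
#'
#' Per-unit loss/gain fraction differences between two landscapes over
#' identical units, with a two-sided exact 2x2 test per unit on the
#' loss counts and Benjamini-Hochberg adjustment.
#'
#' @param landscape_a,landscape_b [cn_frequency_landscape()] outputs
#'   over the same unit set.
#' @return data.frame sorted by decreasing `|delta_loss|`: unit columns
#'   plus `loss_a, loss_b, delta_loss, delta_gain, p, p_adj`.
#' @export
compare_landscapes <- function(landscape_a, landscape_b) {
  check_that(nrow(landscape_a) == nrow(landscape_b) &&
               all(landscape_a$chrom == landscape_b$chrom) &&
               all(landscape_a$start == landscape_b$start) &&
               all(landscape_a$end == landscape_b$end),
             "landscapes computed over different unit sets")
  na <- landscape_a$n_samples_included[1]
  nb <- landscape_b$n_samples_included[1]
  ka <- round(landscape_a$loss_fraction * na)
  kb <- round(landscape_b$loss_fraction * nb)
  p <- vapply(seq_along(ka), function(i) {
    fisher_exact_2x2(ka[i], na - ka[i], kb[i], nb - kb[i])$p_two_sided
  }, numeric(1))
  out <- data.frame(
    chrom = landscape_a$chrom, start = landscape_a$start,
    end = landscape_a$end, gene = landscape_a$gene,
    loss_a = landscape_a$loss_fraction, loss_b = landscape_b$loss_fraction,
    delta_loss = landscape_a$loss_fraction - landscape_b$loss_fraction,
    delta_gain = landscape_a$gain_fraction - landscape_b$gain_fraction,
    p = p, p_adj = bh_adjust(p))
  out[order(-abs(out$delta_loss)), ]
}
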