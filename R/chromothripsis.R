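#' @title Per-chromosome chromothripsis calling
#'
#' @description
#' Operationalises the three defining features of chromothripsis --
#' clustered breakpoints with interleaving normal sequence, oscillation
#' between two or three copy-number states, and fragments rejoined in
#' random orientation and order -- as explicit per-chromosome tests. A
#' region is called at HIGH confidence only when all criteria pass at
#' the configured thresholds (which follow the published high-confidence
#' calling scheme for short-read WGS and are all overridable).
#' @name chromothripsis_caller
NULL

#' Default caller thresholds
#'
#' `min_interleaved` interleaved SVs; oscillation run at least
#' `min_osc_2state` over 2 states (or `min_osc_3state` over 3 states
#' with an interchromosomal join into the region); randomness tests not
#' rejected at `alpha_orient` / `alpha_spacing`. `low_margin` controls
#' how far a single criterion may marginally fail for a LOW call: counts
#' may fall short by at most `low_margin` units, and test p-values may
#' dip to `alpha * low_p_factor`.
#'
#' @return named list of thresholds.
#' @export
chromothripsis_thresholds <- function() {
  list(min_interleaved = 6, min_osc_2state = 7, min_osc_3state = 4,
       alpha_orient = 0.05, alpha_spacing = 0.05,
       low_margin = 2, low_p_factor = 0.2)
}

#' Count mutually interleaved SVs on a chromosome
#'
#' Two intrachromosomal SVs interleave when their breakend intervals
#' cross (overlap without either containing the other). SVs are grouped
#' by the transitive closure of this crossing relation; the count is the
#' size of the largest group with at least two members and the region is
#' its breakend span. Chromosomes with no crossing pair return count 0.
#'
#' @param svs SV table restricted to one chromosome (intrachromosomal
#'   records are used; BND rows are ignored here).
#' @return list with `count`, `region` (`c(start, end)` or `NULL`), and
#'   `member_ids`.
#' @export
interleaved_sv_count <- function(svs) {
  intra <- svs[svs$chrom1 == svs$chrom2, , drop = FALSE]
  n <- nrow(intra)
  if (n < 2) return(list(count = 0L, region = NULL, member_ids = character()))
  a <- intra$pos1; b <- intra$pos2
  # crossing: a_i < a_j < b_i < b_j (in either order of i, j)
  cross <- outer(seq_len(n), seq_len(n), function(i, j) {
    (a[i] < a[j] & a[j] < b[i] & b[i] < b[j]) |
      (a[j] < a[i] & a[i] < b[j] & b[j] < b[i])
  })
  g <- igraph::graph_from_adjacency_matrix(cross, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  if (max(sizes) < 2) return(list(count = 0L, region = NULL,
                                  member_ids = character()))
  biggest <- which.max(sizes)
  members <- which(comp$membership == biggest)
  list(count = length(members),
       region = c(min(a[members]), max(b[members])),
       member_ids = intra$sv_id[members])
}

#' Longest copy-number oscillation run
#'
#' Longest run of adjacent segments whose rounded total copy number
#' alternates within a `max_states`-letter alphabet: every adjacent pair
#' differs and at most `max_states` distinct states occur in the run. A
#' run of one segment (no alternation) has length 1.
#'
#' @param segments segment table (one chromosome, sorted); rounded with
#'   ties at .5 rounding up.
#' @param max_states alphabet size, 2 or 3.
#' @return list with `run_length` and `n_states` (distinct states in the
#'   best run).
#' @export
oscillation_run <- function(segments, max_states = 2) {
  cn <- round_half_up(segments$total_cn)
  n <- length(cn)
  if (n == 0) return(list(run_length = 0L, n_states = 0L))
  best_len <- 1L
  best_states <- 1L
  for (i in seq_len(n)) {
    j <- i
    states <- cn[i]
    while (j < n && cn[j + 1] != cn[j]) {
      cand <- unique(c(states, cn[j + 1]))
      if (length(cand) > max_states) break
      states <- cand
      j <- j + 1L
    }
    if (j - i + 1L > best_len) {
      best_len <- j - i + 1L
      best_states <- length(states)
    }
  }
  list(run_length = best_len, n_states = best_states)
}

#' Goodness-of-fit of join orientations against uniformity
#'
#' Under random rejoining the four orientation classes (deletion-like,
#' duplication-like, head-to-head and tail-to-tail inversion) are
#' equally likely. For up to `exact_max` joins an exact multinomial test
#' is used (sum of probabilities of outcomes no more probable than the
#' observed one); larger counts use the chi-squared approximation. A
#' HIGH chromothripsis call requires NOT rejecting uniformity.
#'
#' @param counts integer vector of length 4.
#' @param exact_max maximum total for the exact path.
#' @return p-value, or `NA` when there are no joins.
#' @export
orientation_randomness <- function(counts, exact_max = 20) {
  check_that(length(counts) == 4, "need counts over the 4 orientation classes")
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  if (n <= exact_max) {
    # enumerate all compositions of n into 4 parts
    obs_p <- stats::dmultinom(counts, prob = rep(0.25, 4))
    p <- 0
    for (x1 in 0:n) for (x2 in 0:(n - x1)) for (x3 in 0:(n - x1 - x2)) {
      x <- c(x1, x2, x3, n - x1 - x2 - x3)
      px <- stats::dmultinom(x, prob = rep(0.25, 4))
      if (px <= obs_p * (1 + 1e-7)) p <- p + px
    }
    min(1, p)
  } else {
    suppressWarnings(stats::chisq.test(counts, p = rep(0.25, 4))$p.value)
  }
}

#' Exponential-spacing test of breakpoint clustering
#'
#' Kolmogorov-Smirnov test of the inter-breakpoint gaps against an
#' exponential distribution with rate `n / span`, operationalising
#' "clustered breakpoints with interleaving normal sequence": genuinely
#' shattered regions have approximately Poisson breakpoints.
#'
#' @param positions breakpoint positions within the candidate region.
#' @return p-value (`NA` for fewer than 3 breakpoints).
#' @export
breakpoint_spacing_test <- function(positions) {
  positions <- sort(unique(positions))
  if (length(positions) < 3) return(NA_real_)
  gaps <- diff(positions)
  rate <- length(positions) / (max(positions) - min(positions))
  suppressWarnings(stats::ks.test(gaps, "pexp", rate = rate)$p.value)
}

orientation_class <- function(strand1, strand2) {
  ifelse(strand1 == "+" & strand2 == "-", "del_like",
  ifelse(strand1 == "-" & strand2 == "+", "dup_like",
  ifelse(strand1 == "+" & strand2 == "+", "inv_h2h", "inv_t2t")))
}

#' Call chromothripsis per chromosome
#'
#' For every chromosome of a sample's SV set: the maximal interleaved
#' cluster defines the candidate region; segments inside it are scored
#' for copy-number oscillation; intrachromosomal joins in the region are
#' tested for orientation uniformity and their breakpoints for
#' exponential spacing. Confidence is `HIGH` when the interleaved count,
#' the oscillation run (2-state rule, or 3-state rule plus an
#' interchromosomal join into the region), and both randomness tests
#' pass; `LOW` when exactly one criterion fails marginally (see
#' [chromothripsis_thresholds()]); otherwise `NONE`.
#'
#' @param profile a [sample_profile()].
#' @param thresholds threshold list.
#' @return data.frame with one row per chromosome that has at least one
#'   interleaved cluster: `chrom, start, end, n_interleaved_sv,
#'   n_oscillating_segments, n_cn_states, orientation_p, spacing_p,
#'   n_interchrom_joins, confidence`.
#' @export
call_chromothripsis <- function(profile,
                                thresholds = chromothripsis_thresholds()) {
  th <- thresholds
  svs <- profile$svs
  out <- list()
  for (ch in unique(c(svs$chrom1, svs$chrom2))) {
    on_ch <- svs[svs$chrom1 == ch | svs$chrom2 == ch, , drop = FALSE]
    il <- interleaved_sv_count(on_ch)
    if (il$count == 0) next
    region <- il$region
    seg <- profile$segments
    seg_in <- seg[seg$chrom == ch & seg$end > region[1] &
                    seg$start < region[2], , drop = FALSE]
    osc <- oscillation_run(seg_in, max_states = 3)
    osc2 <- oscillation_run(seg_in, max_states = 2)
    intra <- on_ch[on_ch$chrom1 == ch & on_ch$chrom2 == ch &
                     on_ch$pos1 >= region[1] & on_ch$pos2 <= region[2], ,
                   drop = FALSE]
    ocls <- orientation_class(intra$strand1, intra$strand2)
    ocounts <- vapply(c("del_like", "dup_like", "inv_h2h", "inv_t2t"),
                      function(k) sum(ocls == k), integer(1))
    orient_p <- orientation_randomness(ocounts)
    spacing_p <- breakpoint_spacing_test(c(intra$pos1, intra$pos2))
    n_bnd_in <- sum(svs$svclass == "BND" &
                      ((svs$chrom1 == ch & svs$pos1 >= region[1] &
                          svs$pos1 <= region[2]) |
                       (svs$chrom2 == ch & svs$pos2 >= region[1] &
                          svs$pos2 <= region[2])))

    crit_interleaved <- il$count >= th$min_interleaved
    crit_osc <- (osc2$run_length >= th$min_osc_2state) ||
      (osc$run_length >= th$min_osc_3state && osc$n_states == 3 &&
         n_bnd_in >= 1)
    crit_orient <- !is.na(orient_p) && orient_p >= th$alpha_orient
    crit_spacing <- !is.na(spacing_p) && spacing_p >= th$alpha_spacing
    passes <- c(crit_interleaved, crit_osc, crit_orient, crit_spacing)

    marginal <- c(
      il$count >= th$min_interleaved - th$low_margin,
      osc2$run_length >= th$min_osc_2state - th$low_margin ||
        (osc$run_length >= th$min_osc_3state - th$low_margin &&
           osc$n_states == 3 && n_bnd_in >= 1),
      !is.na(orient_p) && orient_p >= th$alpha_orient * th$low_p_factor,
      !is.na(spacing_p) && spacing_p >= th$alpha_spacing * th$low_p_factor)

    confidence <- if (all(passes)) {
      "HIGH"
    } else if (sum(!passes) == 1 && all(marginal)) {
      "LOW"
    } else {
      "NONE"
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = region[1], end = region[2],
      n_interleaved_sv = il$count,
      n_oscillating_segments = if (osc2$run_length >= osc$run_length)
        osc2$run_length else osc$run_length,
      n_cn_states = if (osc2$run_length >= osc$run_length) osc2$n_states
        else osc$n_states,
      orientation_p = orient_p, spacing_p = spacing_p,
      n_interchrom_joins = n_bnd_in,
      confidence = confidence)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_interleaved_sv = integer(),
                      n_oscillating_segments = integer(),
                      n_cn_states = integer(), orientation_p = numeric(),
                      spacing_p = numeric(), n_interchrom_joins = integer(),
                      confidence = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort chromothripsis summary
#'
#' @param calls_by_sample named list of [call_chromothripsis()] results.
#' @param confidence which confidence levels count as a call.
#' @return list with `fraction_samples` (samples with any qualifying
#'   call) and `per_chromosome` data.frame of per-chromosome fractions.
#' @export
chromothripsis_cohort_summary <- function(calls_by_sample,
                                          confidence = "HIGH") {
  n <- length(calls_by_sample)
  check_that(n > 0, "empty cohort")
  hits <- lapply(calls_by_sample, function(d) {
    unique(d$chrom[d$confidence %in% confidence])
  })
  frac <- mean(lengths(hits) > 0)
  chroms <- sort(unique(unlist(hits)))
  per_chrom <- data.frame(
    chrom = chroms,
    fraction = vapply(chroms, function(ch) {
      mean(vapply(hits, function(h) ch %in% h, logical(1)))
    }, numeric(1)))
  list(fraction_samples = frac, per_chromosome = per_chrom)
}
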