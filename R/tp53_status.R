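#' @title Locus allele-status classification
#'
#' @description
#' Classifies a gene locus (TP53 by default) as wild-type, monoallelic,
#' or multi-hit from the combination of SNV/indel calls, allele-specific
#' copy loss, copy-neutral LOH, and SV disruption, and resolves whether
#' multi-hit events are biallelic. Folded B-allele frequencies
#' (`max(baf, 1-baf)`) are used throughout so phasing is never required.
#' @name tp53_status
NULL

#' Default allele-status thresholds
#'
#' `tau_baf`: slack below the purity-expected folded BAF `(1+rho)/2`
#' for CN-LOH detection. `tau_cn`: maximum absolute mean log2 ratio for
#' "copy neutral". `n_min`: minimum heterozygous sites per CN-LOH
#' region. `tau_ccf`: slack on the two-SNV copy-fraction sum in
#' [resolve_biallelic()]. None of these is printed in the published
#' analysis; the defaults are chosen to be insensitive at purity 0.4
#' and above.
#'
#' @return named list.
#' @export
allele_status_thresholds <- function() {
  list(tau_baf = 0.05, tau_cn = 0.2, n_min = 20, tau_ccf = 0)
}

#' Detect copy-neutral LOH regions from BAF shift at neutral log2 ratio
#'
#' Returns all maximal site windows (per chromosome) where (a) the mean
#' folded BAF is at least `0.5 + rho/2 - tau_baf` -- the expected
#' major-allele fraction when one parental allele is absent from a
#' tumour of purity `rho` -- (b) the mean log2 coverage ratio of the
#' covering segments stays within `tau_cn` of 0, and (c) at least
#' `n_min` sites are spanned. A window is maximal when no satisfying
#' window strictly contains it. Chromosomes without BAF sites are
#' skipped with a message.
#'
#' @param segments segment table (for per-site log2 lookup).
#' @param baf_sites heterozygous-site BAF table.
#' @param purity tumour purity rho in (0, 1].
#' @param thresholds threshold list (see [allele_status_thresholds()]).
#' @param dict reference dictionary.
#' @return data.frame of regions: `chrom, start, end, mean_major_baf,
#'   mean_log2, n_sites`.
#' @export
detect_cnloh <- function(segments, baf_sites, purity,
                         thresholds = allele_status_thresholds(),
                         dict = NULL) {
  th <- thresholds
  baf_thr <- 0.5 + purity / 2 - th$tau_baf
  out <- list()
  chroms <- unique(segments$chrom)
  for (ch in chroms) {
    sites <- baf_sites[baf_sites$chrom == ch, , drop = FALSE]
    if (!nrow(sites)) {
      message(sprintf("detect_cnloh: no BAF sites on %s, skipped", ch))
      next
    }
    sites <- sites[order(sites$pos), , drop = FALSE]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    # per-site log2 of the covering segment; sites in gaps are dropped
    seg_idx <- findInterval(sites$pos, seg$start)
    covered <- seg_idx >= 1 & sites$pos < seg$end[pmax(seg_idx, 1)]
    sites <- sites[covered, , drop = FALSE]
    if (nrow(sites) < th$n_min) next
    l2 <- seg$log2_ratio[seg_idx[covered]]
    folded <- pmax(sites$baf, 1 - sites$baf)
    n <- nrow(sites)
    cf <- c(0, cumsum(folded))
    cl <- c(0, cumsum(l2))
    # maximal end index per start, then keep starts whose end is a record
    Jmax <- rep(NA_integer_, n)
    for (i in seq_len(n - th$n_min + 1)) {
      j <- (i + th$n_min - 1):n
      len <- j - i + 1
      ok <- (cf[j + 1] - cf[i]) / len >= baf_thr - 1e-12 &
        abs((cl[j + 1] - cl[i]) / len) <= th$tau_cn + 1e-12
      if (any(ok)) Jmax[i] <- j[max(which(ok))]
    }
    best <- -Inf
    for (i in which(!is.na(Jmax))) {
      if (Jmax[i] > best) {
        best <- Jmax[i]
        j <- Jmax[i]
        len <- j - i + 1
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = sites$pos[i], end = sites$pos[j] + 1,
          mean_major_baf = (cf[j + 1] - cf[i]) / len,
          mean_log2 = (cl[j + 1] - cl[i]) / len,
          n_sites = len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), mean_major_baf = numeric(),
                      mean_log2 = numeric(), n_sites = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

is_indel <- function(variants) {
  nchar(variants$ref) != nchar(variants$alt) |
    (!is.na(variants$effect) & grepl("frameshift|indel", variants$effect,
                                     ignore.case = TRUE))
}

#' Classify a locus as wild-type / monoallelic / multi-hit
#'
#' Hit mechanisms are assembled from (i) SNV/indel calls overlapping
#' the locus, (ii) segments with minor allele copy number 0 and total
#' below 2 overlapping the locus (allele loss -- a subclonal dip with a
#' retained minor allele does not count), (iii) overlap with a detected
#' CN-LOH region, and (iv) any SV breakend inside the locus. The
#' category is `MULTI_HIT` when there are two or more SNV/indel hits,
#' or at least one SNV/indel combined with loss/CN-LOH/SV disruption,
#' or copy loss co-occurring with SV disruption; `MONOALLELIC` when
#' exactly one mechanism is present; `WILD_TYPE` otherwise. Multi-hit
#' calls are then passed through [resolve_biallelic()].
#'
#' @param locus list with `chrom, start, end` and optional `gene`.
#' @param profile a [sample_profile()].
#' @param cnloh optional precomputed [detect_cnloh()] table.
#' @param thresholds threshold list.
#' @return object of class `allele_status_call`: list with `locus`,
#'   `gene`, `snv_hits`, `mechanisms`, `category`, `biallelic`,
#'   `evidence_notes`.
#' @export
classify_locus <- function(locus, profile, cnloh = NULL,
                           thresholds = allele_status_thresholds()) {
  check_that(locus$chrom %in% profile$dict$chroms$chrom,
             "locus chromosome %s not in reference dictionary", locus$chrom)
  if (is.null(cnloh)) {
    cnloh <- detect_cnloh(profile$segments, profile$baf_sites,
                          profile$purity, thresholds)
  }
  sv <- profile$small_variants
  hits <- sv[sv$chrom == locus$chrom & sv$pos >= locus$start &
               sv$pos < locus$end, , drop = FALSE]
  mechanisms <- character(0)
  if (nrow(hits)) {
    mechanisms <- union(mechanisms,
                        ifelse(is_indel(hits), "INDEL", "SNV"))
  }
  seg <- profile$segments
  loss <- seg[seg$chrom == locus$chrom & seg$end > locus$start &
                seg$start < locus$end &
                round_half_up(seg$minor_cn) == 0 &
                round_half_up(seg$total_cn) < 2, , drop = FALSE]
  if (nrow(loss)) mechanisms <- union(mechanisms, "CN_LOSS")
  if (nrow(cnloh)) {
    hit_loh <- cnloh[cnloh$chrom == locus$chrom & cnloh$end > locus$start &
                       cnloh$start < locus$end, , drop = FALSE]
    if (nrow(hit_loh)) mechanisms <- union(mechanisms, "CN_LOH")
  }
  svs <- profile$svs
  bend_in <- (svs$chrom1 == locus$chrom & svs$pos1 >= locus$start &
                svs$pos1 < locus$end) |
    (svs$chrom2 == locus$chrom & svs$pos2 >= locus$start &
       svs$pos2 < locus$end)
  if (any(bend_in)) mechanisms <- union(mechanisms, "SV_DISRUPTION")

  n_small <- nrow(hits)
  cn_mech <- intersect(mechanisms, c("CN_LOSS", "CN_LOH", "SV_DISRUPTION"))
  category <- if (n_small >= 2 ||
                  (n_small >= 1 && length(cn_mech) > 0) ||
                  all(c("CN_LOSS", "SV_DISRUPTION") %in% mechanisms)) {
    "MULTI_HIT"
  } else if (n_small >= 1 || length(mechanisms) > 0) {
    "MONOALLELIC"
  } else {
    "WILD_TYPE"
  }
  call <- structure(list(
    locus = locus, gene = if (is.null(locus$gene)) NA_character_ else locus$gene,
    snv_hits = hits, mechanisms = mechanisms, category = category,
    biallelic = "NOT_APPLICABLE",
    evidence_notes = sprintf("%d small-variant hit(s); mechanisms: %s",
                             n_small,
                             if (length(mechanisms)) {
                               paste(mechanisms, collapse = "+")
                             } else "none")
  ), class = "allele_status_call")
  if (category == "MULTI_HIT") call <- resolve_biallelic(call, profile,
                                                         thresholds)
  call
}

#' @exportS3Method base::print
print.allele_status_call <- function(x, ...) {
  cat(sprintf("<allele_status_call %s: %s (%s), biallelic=%s>\n",
              x$gene, x$category,
              paste(x$mechanisms, collapse = "+"), x$biallelic))
  invisible(x)
}

#' Resolve biallelic status of a multi-hit call
#'
#' `BIALLELIC` when (a) an SNV/indel co-occurs with copy loss, CN-LOH,
#' or SV disruption of the other allele (the second allele is
#' physically lost or broken), (b) copy loss and SV disruption
#' co-occur, (c) two variants carry a trans `phase` annotation, or
#' (d) the two strongest SNV/indel hits occupy more tumour copies than
#' one allele can hold: with locus copy number `CN`, the fraction of
#' tumour copies carrying a variant is
#' `f = vaf * (rho * CN + 2 (1 - rho)) / (rho * CN)`; two variants
#' confined to one of two alleles each have `f <= 1/2`, so
#' `f1 + f2 > 1 + tau_ccf` excludes the single-allele configuration.
#' Otherwise `UNRESOLVED` (the published analyses likewise leave a
#' minority of two-SNV cases unresolved on short reads).
#'
#' @param call an `allele_status_call` with category `MULTI_HIT`.
#' @param profile the sample's [sample_profile()].
#' @param thresholds threshold list (uses `tau_ccf`).
#' @return the call with the `biallelic` field filled.
#' @export
resolve_biallelic <- function(call, profile,
                              thresholds = allele_status_thresholds()) {
  check_that(call$category == "MULTI_HIT",
             "resolve_biallelic requires a MULTI_HIT call")
  mech <- call$mechanisms
  has_small <- any(c("SNV", "INDEL") %in% mech)
  second_allele_gone <- any(c("CN_LOSS", "CN_LOH", "SV_DISRUPTION") %in% mech)
  if ((has_small && second_allele_gone) ||
      all(c("CN_LOSS", "SV_DISRUPTION") %in% mech)) {
    call$biallelic <- "BIALLELIC"
    return(call)
  }
  hits <- call$snv_hits
  if (nrow(hits) >= 2) {
    if (!is.null(hits$phase) && any(hits$phase %in% "trans")) {
      call$biallelic <- "BIALLELIC"
      return(call)
    }
    rho <- profile$purity
    seg <- profile$segments
    mid <- (call$locus$start + call$locus$end) / 2
    cov <- seg[seg$chrom == call$locus$chrom & seg$start <= mid &
                 seg$end > mid, , drop = FALSE]
    cn <- if (nrow(cov)) max(1, round_half_up(cov$total_cn[1])) else 2
    f <- hits$vaf * (rho * cn + 2 * (1 - rho)) / (rho * cn)
    top2 <- sort(f, decreasing = TRUE)[1:2]
    call$biallelic <- if (sum(top2) > 1 + thresholds$tau_ccf) {
      "BIALLELIC"
    } else {
      "UNRESOLVED"
    }
    return(call)
  }
  call$biallelic <- "UNRESOLVED"
  call
}
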