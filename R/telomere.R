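#' @title Telomere content, variant repeats, and interstitial insertions
#'
#' @description
#' Telomere analytics from aligned reads: content as telomeric reads per
#' GC-content-matched million reads (TRPM), tumour/normal ratios,
#' singleton telomere-variant-repeat (TVR) profiling, and detection of
#' somatic interstitial telomere insertions from soft-clipped reads.
#' @name telomere_analysis
NULL

#' Canonical and variant telomeric hexamers
#'
#' The t-type repeat is TTAGGG; `default_tvr_set()` is the standard
#' panel of variant hexamers accepted during read classification.
#'
#' @return character vector of hexamers.
#' @export
t_type_hexamer <- function() "TTAGGG"

#' @rdname t_type_hexamer
#' @export
default_tvr_set <- function() {
  c("TCAGGG", "TGAGGG", "TTGGGG", "TTCGGG", "TTTGGG",
    "ATAGGG", "CATGGG", "CTAGGG", "GTAGGG", "TAAGGG")
}

# reverse-complement via Biostrings, vectorised
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# hexamer matrix (reads x positions) for one frame, seqs all same length
frame_hexamers <- function(seqs, L, frame) {
  n_h <- (L - frame) %/% 6
  if (n_h < 1) return(NULL)
  starts <- frame + 6 * (seq_len(n_h) - 1) + 1
  hex <- vapply(starts, function(s) substring(seqs, s, s + 5),
                character(length(seqs)))
  if (is.null(dim(hex))) hex <- matrix(hex, nrow = length(seqs))
  hex
}

# count accepted hexamers per read for one frame
frame_counts <- function(seqs, L, frame, accepted) {
  hex <- frame_hexamers(seqs, L, frame)
  if (is.null(hex)) return(list(count = integer(length(seqs)), hex = NULL))
  acc <- matrix(hex %in% accepted, nrow = length(seqs))
  list(count = rowSums(acc), hex = hex)
}

#' Classify reads as telomeric and decompose them into hexamers
#'
#' Both orientations are scanned (G-type hexamers on the read, and on
#' its reverse complement for CCCTAA-type reads) across all six frames;
#' the richest frame wins. A read of length `L` is telomeric when its
#' best frame contains at least `ceiling(6 L / 100)` hexamers from the
#' accepted set (t-type plus the TVR panel). Decompositions are returned
#' in G-orientation for telomeric reads so TVR contexts can be profiled.
#' Reads containing non-ACGT characters are skipped (`NA` in the output).
#'
#' @param seqs character vector of read sequences.
#' @param tvr_set accepted variant hexamers (default [default_tvr_set()]).
#' @param min_hexamers optional fixed threshold overriding the
#'   length-scaled default.
#' @return list with `telomeric` (logical, `NA` for skipped reads),
#'   `n_accepted` (best-frame accepted-hexamer count), and
#'   `decomposition` (list of hexamer vectors, `NULL` for non-telomeric
#'   reads).
#' @export
classify_telomeric_read <- function(seqs, tvr_set = default_tvr_set(),
                                    min_hexamers = NULL) {
  n <- length(seqs)
  accepted <- c(t_type_hexamer(), tvr_set)
  telomeric <- logical(n)
  n_accepted <- integer(n)
  decomposition <- vector("list", n)
  valid <- grepl("^[ACGT]+$", seqs) & nchar(seqs) >= 6
  if (any(!valid)) {
    message(sprintf("classify_telomeric_read: skipping %d read(s) with non-ACGT characters or length < 6",
                    sum(!valid)))
    telomeric[!valid] <- NA
  }
  for (L in unique(nchar(seqs[valid]))) {
    idx <- which(valid & nchar(seqs) == L)
    thr_L <- if (is.null(min_hexamers)) ceiling(6 * L / 100) else min_hexamers
    # cheap lower-bound screen: every accepted hexamer contains GGG (or
    # CCC on the complementary strand), so a read with fewer GGG + CCC
    # occurrences than the hexamer threshold can never classify
    dss <- Biostrings::DNAStringSet(seqs[idx])
    ggg <- Biostrings::vcountPattern("GGG", dss) +
      Biostrings::vcountPattern("CCC", dss)
    idx <- idx[ggg >= thr_L]
    if (!length(idx)) next
    fwd <- seqs[idx]
    rev <- revcomp(fwd)
    best_count <- integer(length(idx))
    best_orient <- rep("F", length(idx))
    best_frame <- integer(length(idx))
    for (orient in c("F", "R")) {
      s <- if (orient == "F") fwd else rev
      for (f in 0:5) {
        cnt <- frame_counts(s, L, f, accepted)$count
        better <- cnt > best_count
        if (any(better)) {
          best_count[better] <- cnt[better]
          best_orient[better] <- orient
          best_frame[better] <- f
        }
      }
    }
    thr <- if (is.null(min_hexamers)) ceiling(6 * L / 100) else min_hexamers
    tel <- best_count >= thr
    telomeric[idx] <- tel
    n_accepted[idx] <- best_count
    # decompose only the telomeric reads, in their winning orientation/frame
    for (k in which(tel)) {
      s <- if (best_orient[k] == "F") fwd[k] else rev[k]
      decomposition[[idx[k]]] <-
        frame_hexamers(s, L, best_frame[k])[1, ]
    }
  }
  list(telomeric = telomeric, n_accepted = n_accepted,
       decomposition = decomposition)
}

#' GC-matched telomere content (TRPM)
#'
#' The denominator counts reads whose realised GC fraction lies in the
#' telomere-like window (default 0.48-0.52); telomeric reads are counted
#' regardless of their own GC. `trpm = n_telomeric / n_gc_matched * 1e6`.
#'
#' @param reads data.frame with a `seq` column (as from [read_sam()]).
#' @param gc_low,gc_high GC window bounds (inclusive).
#' @param tvr_set accepted variant hexamers.
#' @param sample_id,tissue carried through to the result.
#' @return object of class `telomere_metrics`: list with
#'   `n_gc_matched_reads`, `n_telomeric_reads`, `trpm`,
#'   `singleton_tvr_counts`, `singleton_tvr_norm`, `decomposition`.
#' @export
telomere_content <- function(reads, gc_low = 0.48, gc_high = 0.52,
                             tvr_set = default_tvr_set(),
                             sample_id = NA_character_,
                             tissue = NA_character_) {
  check_that(gc_low < gc_high, "invalid GC window")
  check_that(nrow(reads) > 0, "no reads supplied")
  gc <- gc_fraction(reads$seq)
  n_gc <- sum(gc >= gc_low & gc <= gc_high)
  check_that(n_gc > 0, "no GC-matched reads in window [%.2f,%.2f]; TRPM undefined",
             gc_low, gc_high)
  cls <- classify_telomeric_read(reads$seq, tvr_set = tvr_set)
  n_tel <- sum(cls$telomeric, na.rm = TRUE)
  decomp <- cls$decomposition[which(cls$telomeric)]
  singleton <- singleton_tvr_profile(decomp, tvr_set = tvr_set)
  structure(list(
    sample_id = sample_id, tissue = tissue,
    n_gc_matched_reads = n_gc, n_telomeric_reads = n_tel,
    trpm = n_tel / n_gc * 1e6,
    singleton_tvr_counts = singleton,
    singleton_tvr_norm = singleton / n_gc * 1e6,
    decomposition = decomp
  ), class = "telomere_metrics")
}

#' @exportS3Method base::print
print.telomere_metrics <- function(x, ...) {
  cat(sprintf("<telomere_metrics %s/%s: %d telomeric / %d GC-matched reads, TRPM %.1f>\n",
              x$sample_id, x$tissue, x$n_telomeric_reads,
              x$n_gc_matched_reads, x$trpm))
  invisible(x)
}

#' Tumour/normal telomere content comparison
#'
#' @param metrics_t,metrics_n `telomere_metrics` for tumour and normal.
#' @return list with `ratio` (`NA` when normal TRPM is 0) and
#'   `difference` (tumour minus normal, always reported).
#' @export
tumor_normal_ratio <- function(metrics_t, metrics_n) {
  ratio <- if (metrics_n$trpm == 0) NA_real_ else metrics_t$trpm / metrics_n$trpm
  list(ratio = ratio, difference = metrics_t$trpm - metrics_n$trpm)
}

#' Singleton TVR counts
#'
#' A variant-hexamer occurrence is a singleton when it is flanked by at
#' least three consecutive t-type (TTAGGG) hexamers on each side within
#' the same read.
#'
#' @param decompositions list of hexamer vectors (G-orientation), as
#'   produced by [classify_telomeric_read()].
#' @param tvr_set variant hexamers to profile.
#' @return named integer vector: singleton count per variant hexamer.
#' @export
singleton_tvr_profile <- function(decompositions,
                                  tvr_set = default_tvr_set()) {
  counts <- stats::setNames(integer(length(tvr_set)), tvr_set)
  ttype <- t_type_hexamer()
  for (hex in decompositions) {
    m <- length(hex)
    if (m < 7) next
    is_t <- hex == ttype
    is_v <- hex %in% tvr_set
    for (i in which(is_v)) {
      if (i >= 4 && i <= m - 3 &&
          all(is_t[(i - 3):(i - 1)]) && all(is_t[(i + 1):(i + 3)])) {
        counts[hex[i]] <- counts[hex[i]] + 1L
      }
    }
  }
  counts
}

# clip loci of reads qualifying as telomeric-clipped; returns df
clipped_telomeric_loci <- function(reads, min_clip, clip_tel_frac, tvr_set) {
  out <- list()
  accepted <- c(t_type_hexamer(), tvr_set)
  for (i in seq_len(nrow(reads))) {
    clips <- cigar_clips(reads$cigar[i])
    for (side in c("left", "right")) {
      len <- clips[[side]]
      if (len < min_clip) next
      seqlen <- nchar(reads$seq[i])
      clip_seq <- if (side == "left") {
        substring(reads$seq[i], 1, len)
      } else {
        substring(reads$seq[i], seqlen - len + 1, seqlen)
      }
      ops <- cigar_ops(reads$cigar[i])
      ref_len <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
      locus <- if (side == "left") reads$pos[i] else reads$pos[i] + ref_len
      n_h <- nchar(clip_seq) %/% 6
      if (n_h < 1) next
      best <- 0
      for (f in 0:5) {
        fc <- frame_counts(clip_seq, nchar(clip_seq), f, accepted)
        best <- max(best, fc$count)
      }
      frac <- best / n_h
      if (frac >= clip_tel_frac) {
        out[[length(out) + 1]] <- data.frame(
          chrom = reads$chrom[i], locus = locus, frac = frac)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), locus = numeric(),
                      frac = numeric()))
  }
  do.call(rbind, out)
}

#' Detect somatic interstitial telomere insertions
#'
#' Scans tumour reads for soft-clipped tails (at least `min_clip` bases)
#' whose hexamer content is at least `clip_tel_frac` telomeric, clusters
#' the clip loci within `cluster_bp`, and calls a locus when it is
#' supported by `min_support` or more tumour reads with no qualifying
#' read in the matched normal. Chromosome termini (outermost
#' `termini_mask` bases, where genuine telomere sequence lives) are
#' masked. Calls are annotated with the distance to the nearest SV
#' breakend and a flag for proximity (10 kb) to a high-confidence
#' chromothripsis region.
#'
#' @param tumor_reads,normal_reads read data.frames ([read_sam()]);
#'   `normal_reads = NULL` emits calls flagged as un-subtracted.
#' @param svs optional SV table for breakend-distance annotation.
#' @param chromothripsis_calls optional data.frame with `chrom`, `start`,
#'   `end` of high-confidence chromothripsis regions.
#' @param dict reference dictionary (for the termini mask).
#' @param min_clip minimum soft-clip length (bp).
#' @param clip_tel_frac minimum telomeric fraction of the clip hexamers.
#' @param min_support minimum supporting tumour reads.
#' @param cluster_bp clustering radius for clip loci.
#' @param termini_mask masked bases at each chromosome end.
#' @param tvr_set accepted variant hexamers.
#' @return data.frame with one row per call: `chrom, pos,
#'   n_support_tumor, n_support_normal, clipped_telomeric_fraction,
#'   nearest_sv_distance_bp, within_chromothripsis_10kb, subtracted`.
#' @export
detect_interstitial_insertions <- function(tumor_reads, normal_reads = NULL,
                                           svs = NULL,
                                           chromothripsis_calls = NULL,
                                           dict = toy_genome(),
                                           min_clip = 12,
                                           clip_tel_frac = 0.8,
                                           min_support = 3,
                                           cluster_bp = 50,
                                           termini_mask = 5e5,
                                           tvr_set = default_tvr_set()) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      n_support_tumor = integer(),
                      n_support_normal = integer(),
                      clipped_telomeric_fraction = numeric(),
                      nearest_sv_distance_bp = numeric(),
                      within_chromothripsis_10kb = logical(),
                      subtracted = logical())
  tl <- clipped_telomeric_loci(tumor_reads, min_clip, clip_tel_frac, tvr_set)
  if (nrow(tl) == 0) return(empty)
  nl <- if (is.null(normal_reads)) NULL else {
    clipped_telomeric_loci(normal_reads, min_clip, clip_tel_frac, tvr_set)
  }
  calls <- list()
  for (ch in unique(tl$chrom)) {
    loci <- sort(tl$locus[tl$chrom == ch])
    grp <- cumsum(c(1, diff(loci) > cluster_bp))
    for (g in unique(grp)) {
      pos <- stats::median(loci[grp == g])
      support <- sum(grp == g)
      if (support < min_support) next
      if (pos < termini_mask || pos > chrom_length(dict, ch) - termini_mask) next
      n_norm <- if (is.null(nl)) 0L else {
        sum(nl$chrom == ch & abs(nl$locus - pos) <= cluster_bp)
      }
      if (!is.null(nl) && n_norm > 0) next
      frac <- mean(tl$frac[tl$chrom == ch & abs(tl$locus - pos) <= cluster_bp])
      sv_dist <- NA_real_
      if (!is.null(svs) && nrow(svs)) {
        bends <- c(svs$pos1[svs$chrom1 == ch], svs$pos2[svs$chrom2 == ch])
        if (length(bends)) sv_dist <- min(abs(bends - pos))
      }
      in_ct <- FALSE
      if (!is.null(chromothripsis_calls) && nrow(chromothripsis_calls)) {
        cc <- chromothripsis_calls[chromothripsis_calls$chrom == ch, ,
                                   drop = FALSE]
        if (nrow(cc)) {
          in_ct <- any(pos >= cc$start - 1e4 & pos <= cc$end + 1e4)
        }
      }
      calls[[length(calls) + 1]] <- data.frame(
        chrom = ch, pos = pos, n_support_tumor = support,
        n_support_normal = n_norm,
        clipped_telomeric_fraction = frac,
        nearest_sv_distance_bp = sv_dist,
        within_chromothripsis_10kb = in_ct,
        subtracted = !is.null(nl))
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
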