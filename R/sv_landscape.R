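#' @title Structural-variant landscapes
#'
#' @description
#' Per-sample SV class counts, proximity clustering of SVs into complex
#' events, cluster-size summaries, and cohort breakpoint frequency in
#' fixed genomic windows.
#' @name sv_landscape
NULL

#' Count SVs by class
#'
#' @param profile a [sample_profile()] (or an SV table).
#' @return named integer vector over `DEL, DUP, INS, INV, BND`; sums to
#'   the total SV count.
#' @export
count_sv_classes <- function(profile) {
  svs <- if (inherits(profile, "sample_profile")) profile$svs else profile
  vapply(sv_classes, function(k) sum(svs$svclass == k), integer(1))
}

#' Cluster SVs into complex events by breakend proximity
#'
#' Two SVs are linked when any breakend of one lies within
#' `proximity_bp` of any breakend of the other on the same chromosome;
#' clusters are the transitive closure of this relation, so both
#' breakends of an SV always co-cluster and the clusters partition the
#' SV set. The published analyses delegate this step to a dedicated
#' clustering tool whose linkage distance is not printed; 1 Mb is this
#' package's documented default.
#'
#' @param svs SV table.
#' @param proximity_bp linkage distance in bp (> 0).
#' @return data.frame with one row per SV: `sv_id, cluster_id`, plus a
#'   `"clusters"` attribute data.frame (`cluster_id, size`) and a
#'   `"footprint"` attribute (per-cluster breakend span intervals).
#' @export
cluster_complex <- function(svs, proximity_bp = 1e6) {
  check_that(proximity_bp > 0, "proximity_bp must be positive")
  n <- nrow(svs)
  if (n == 0) {
    out <- data.frame(sv_id = character(), cluster_id = integer())
    attr(out, "clusters") <- data.frame(cluster_id = integer(),
                                        size = integer())
    return(out)
  }
  # one node per SV; edges between SVs with nearby breakends
  bends <- rbind(
    data.frame(sv = seq_len(n), chrom = svs$chrom1, pos = svs$pos1),
    data.frame(sv = seq_len(n), chrom = svs$chrom2, pos = svs$pos2))
  edges <- list()
  for (ch in unique(bends$chrom)) {
    b <- bends[bends$chrom == ch, , drop = FALSE]
    b <- b[order(b$pos), , drop = FALSE]
    if (nrow(b) < 2) next
    # chain consecutive breakends within the linkage distance; the
    # transitive closure makes chaining equivalent to all-pairs linking
    close <- which(diff(b$pos) <= proximity_bp)
    if (length(close)) {
      edges[[length(edges) + 1]] <- cbind(b$sv[close], b$sv[close + 1])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  membership <- igraph::components(g)$membership
  out <- data.frame(sv_id = svs$sv_id, cluster_id = membership)
  sizes <- as.data.frame(table(membership), stringsAsFactors = FALSE)
  names(sizes) <- c("cluster_id", "size")
  sizes$cluster_id <- as.integer(sizes$cluster_id)
  attr(out, "clusters") <- sizes
  fp <- lapply(split(seq_len(n), membership), function(id) {
    bb <- bends[bends$sv %in% id, , drop = FALSE]
    do.call(rbind, lapply(split(bb, bb$chrom), function(x) {
      data.frame(chrom = x$chrom[1], start = min(x$pos),
                 end = max(x$pos) + 1)
    }))
  })
  attr(out, "footprint") <- fp
  out
}

#' Cohort SV breakpoint frequency in fixed windows
#'
#' Chromosomes are tiled with non-overlapping windows of `window_bp`;
#' each sample contributes at most once per window regardless of how
#' many of its breakends fall there. Both breakends of every SV are
#' windowed (an SV can hit two windows).
#'
#' @param profiles list of [sample_profile()] objects (the cohort).
#' @param window_bp window width (default 100 kb).
#' @param dict reference dictionary.
#' @return data.frame `chrom, start, end, n_samples_hit, fraction`,
#'   restricted to windows hit by at least one sample.
#' @export
window_breakpoint_frequency <- function(profiles, window_bp = 1e5,
                                        dict = NULL) {
  check_that(window_bp > 0, "window_bp must be positive")
  check_that(length(profiles) > 0, "empty cohort")
  if (is.null(dict)) dict <- profiles[[1]]$dict
  hits <- list()
  for (p in profiles) {
    svs <- p$svs
    if (!nrow(svs)) next
    bend <- rbind(data.frame(chrom = svs$chrom1, pos = svs$pos1),
                  data.frame(chrom = svs$chrom2, pos = svs$pos2))
    win <- unique(data.frame(chrom = bend$chrom,
                             idx = floor(bend$pos / window_bp)))
    win$sample <- p$sample_id
    hits[[length(hits) + 1]] <- win
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_samples_hit = integer(),
                      fraction = numeric()))
  }
  all_hits <- do.call(rbind, hits)
  agg <- stats::aggregate(sample ~ chrom + idx, data = all_hits,
                          FUN = function(s) length(unique(s)))
  out <- data.frame(
    chrom = agg$chrom,
    start = agg$idx * window_bp,
    end = pmin((agg$idx + 1) * window_bp, chrom_length(dict, agg$chrom)),
    n_samples_hit = agg$sample,
    fraction = agg$sample / length(profiles))
  out[order(out$chrom, out$start), ]
}

#' Cohort summary of complex-cluster sizes
#'
#' Per sample, the histogram of cluster sizes and whether the sample
#' carries any complex event with more than 20 (resp. more than 100)
#' member SVs; the thresholds are strict inequalities as published.
#'
#' @param profiles list of [sample_profile()] objects.
#' @param proximity_bp linkage distance passed to [cluster_complex()].
#' @return list with `per_sample` (data.frame `sample_id, n_sv,
#'   largest_cluster, any_gt20, any_gt100`), `n_samples_gt20`,
#'   `n_samples_gt100`, and `fraction_sv_in_complex` (fraction of all
#'   cohort SVs belonging to clusters of 20 or more members).
#' @export
cluster_size_summary <- function(profiles, proximity_bp = 1e6) {
  rows <- lapply(profiles, function(p) {
    cl <- cluster_complex(p$svs, proximity_bp)
    sizes <- attr(cl, "clusters")$size
    largest <- if (length(sizes)) max(sizes) else 0L
    n_complex_sv <- sum(sizes[sizes >= 20])
    data.frame(sample_id = p$sample_id, n_sv = nrow(p$svs),
               largest_cluster = largest,
               n_sv_in_complex = n_complex_sv,
               any_gt20 = largest > 20, any_gt100 = largest > 100)
  })
  per_sample <- do.call(rbind, rows)
  total_sv <- sum(per_sample$n_sv)
  list(per_sample = per_sample,
       n_samples_gt20 = sum(per_sample$any_gt20),
       n_samples_gt100 = sum(per_sample$any_gt100),
       fraction_sv_in_complex = if (total_sv > 0) {
         sum(per_sample$n_sv_in_complex) / total_sv
       } else NA_real_)
}
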