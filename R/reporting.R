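#' @title Cohort reporting and pipeline driver
#'
#' @description
#' Runs every analysis stage over a cohort in dependency order (allele
#' status, SV landscape, chromothripsis, copy-number landscape,
#' telomere analytics, cross-cohort statistics), assembles one row per
#' sample plus cohort aggregates, and re-checks that every aggregate is
#' recomputable from the per-sample rows before returning.
#' @name reporting
NULL

read_sample_reads <- function(profile, tissue) {
  field <- paste0(tissue, "_reads")
  if (!is.null(profile[[field]])) return(profile[[field]])
  path <- profile[[paste0(tissue, "_reads_path")]]
  if (is.null(path) || is.na(path) || !file.exists(path)) return(NULL)
  read_sam(path)
}

#' Run the full landscape pipeline over a cohort
#'
#' Stage failures are isolated per sample (recorded in `errors`), not
#' fatal to the cohort. Aggregates are recomputed from the per-sample
#' rows inside the pipeline as a consistency assertion.
#'
#' @param profiles list of [sample_profile()] objects, or a sample
#'   sheet path.
#' @param locus classification locus (default the toy TP53 locus when
#'   the first profile uses the toy dictionary, else TP53 on GRCh38).
#' @param config optional list overriding thresholds:
#'   `allele_thresholds`, `chromothripsis_thresholds`, `proximity_bp`,
#'   `window_bp`, `insertion` (list of [detect_interstitial_insertions()]
#'   arguments).
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return list of class `cohort_report`: `per_sample` data.frame,
#'   `aggregates` list, `errors`, `provenance`.
#' @export
run_pipeline <- function(profiles, locus = NULL, config = list(),
                         out_dir = NULL) {
  if (is.character(profiles)) profiles <- read_sample_sheet(profiles)
  check_that(length(profiles) > 0, "empty cohort")
  dict <- profiles[[1]]$dict
  if (is.null(locus)) {
    locus <- if ("chrT3" %in% dict$chroms$chrom) tp53_locus_toy() else
      list(chrom = "chr17", start = 7668400, end = 7687549, gene = "TP53")
  }
  ath <- config$allele_thresholds
  if (is.null(ath)) ath <- allele_status_thresholds()
  cth <- config$chromothripsis_thresholds
  if (is.null(cth)) cth <- chromothripsis_thresholds()
  proximity_bp <- if (is.null(config$proximity_bp)) 1e6 else
    config$proximity_bp
  window_bp <- if (is.null(config$window_bp)) 1e5 else config$window_bp

  rows <- list()
  errors <- list()
  ct_calls <- list()
  tel_metrics <- list()
  insertions <- list()
  for (p in profiles) {
    row <- tryCatch({
      status <- classify_locus(locus, p, thresholds = ath)
      classes <- count_sv_classes(p)
      cl <- cluster_complex(p$svs, proximity_bp)
      largest <- if (nrow(attr(cl, "clusters"))) {
        max(attr(cl, "clusters")$size)
      } else 0L
      ct <- call_chromothripsis(p, thresholds = cth)
      ct_calls[[p$sample_id]] <- ct
      ct_chroms <- unique(ct$chrom[ct$confidence == "HIGH"])

      trpm_t <- trpm_n <- NA_real_
      n_ins <- NA_integer_
      treads <- read_sample_reads(p, "tumor")
      nreads <- read_sample_reads(p, "normal")
      if (!is.null(treads)) {
        ins_cfg <- config$insertion
        if (is.null(ins_cfg)) ins_cfg <- list()
        mt <- telomere_content(treads, sample_id = p$sample_id,
                               tissue = "tumor")
        tel_metrics[[paste0(p$sample_id, "_T")]] <- mt
        trpm_t <- mt$trpm
        if (!is.null(nreads)) {
          mn <- telomere_content(nreads, sample_id = p$sample_id,
                                 tissue = "normal")
          tel_metrics[[paste0(p$sample_id, "_N")]] <- mn
          trpm_n <- mn$trpm
        }
        hi_ct <- ct[ct$confidence == "HIGH", , drop = FALSE]
        ins <- do.call(detect_interstitial_insertions, c(
          list(tumor_reads = treads, normal_reads = nreads,
               svs = p$svs, chromothripsis_calls = hi_ct, dict = dict),
          ins_cfg))
        insertions[[p$sample_id]] <- ins
        n_ins <- nrow(ins)
      }
      data.frame(
        sample_id = p$sample_id, cohort_label = p$cohort_label,
        purity = p$purity,
        tp53_category = status$category,
        tp53_biallelic = status$biallelic,
        tp53_mechanisms = paste(status$mechanisms, collapse = "+"),
        n_sv = sum(classes),
        n_del = classes[["DEL"]], n_dup = classes[["DUP"]],
        n_ins_sv = classes[["INS"]], n_inv = classes[["INV"]],
        n_bnd = classes[["BND"]],
        largest_cluster = largest,
        chromothripsis_chroms = paste(ct_chroms, collapse = ","),
        n_chromothripsis_chroms = length(ct_chroms),
        trpm_tumor = trpm_t, trpm_normal = trpm_n,
        trpm_ratio = if (!is.na(trpm_t) && !is.na(trpm_n) && trpm_n > 0) {
          trpm_t / trpm_n
        } else NA_real_,
        n_telomere_insertions = n_ins)
    }, error = function(e) {
      errors[[p$sample_id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) rows[[p$sample_id]] <- row
  }
  check_that(length(rows) > 0, "every sample failed")
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL

  aggregates <- list()
  tp53_rows <- per_sample[startsWith(per_sample$cohort_label, "TP53"), ,
                          drop = FALSE]
  if (nrow(tp53_rows)) {
    aggregates$multihit_fraction <-
      mean(tp53_rows$tp53_category == "MULTI_HIT")
    aggregates$biallelic_fraction_of_multihit <-
      mean(tp53_rows$tp53_biallelic[tp53_rows$tp53_category ==
                                      "MULTI_HIT"] == "BIALLELIC")
    aggregates$chromothripsis_fraction <-
      mean(tp53_rows$n_chromothripsis_chroms > 0)
    aggregates$median_sv_count <- stats::median(tp53_rows$n_sv)
    aggregates$n_samples_gt20 <- sum(tp53_rows$largest_cluster > 20)
    aggregates$n_samples_gt100 <- sum(tp53_rows$largest_cluster > 100)
  }
  if (length(ct_calls)) {
    aggregates$chromothripsis_by_chrom <-
      chromothripsis_cohort_summary(ct_calls)$per_chromosome
  }
  cbf_rows <- per_sample[per_sample$cohort_label == "CBF_AML", ,
                         drop = FALSE]
  if (nrow(tp53_rows) && nrow(cbf_rows) && any(!is.na(per_sample$trpm_tumor))) {
    sh_t <- tp53_rows$trpm_normal - tp53_rows$trpm_tumor
    sh_c <- cbf_rows$trpm_normal - cbf_rows$trpm_tumor
    aggregates$telomere_shortening <- list(
      mean_tp53 = mean(sh_t, na.rm = TRUE),
      mean_cbf = mean(sh_c, na.rm = TRUE))
    a <- sum(tp53_rows$n_telomere_insertions > 0, na.rm = TRUE)
    c0 <- sum(cbf_rows$n_telomere_insertions > 0, na.rm = TRUE)
    aggregates$insertion_fisher <- fisher_exact_2x2(
      a, nrow(tp53_rows) - a, c0, nrow(cbf_rows) - c0)
  }
  if (nrow(tp53_rows) && nrow(cbf_rows)) {
    aggregates$sv_burden_wilcoxon <-
      wilcoxon_rank_sum(tp53_rows$n_sv, cbf_rows$n_sv)
  }

  # aggregate/row consistency assertion (runs inside the pipeline)
  if (!is.null(aggregates$multihit_fraction)) {
    stopifnot(isTRUE(all.equal(
      aggregates$multihit_fraction,
      mean(tp53_rows$tp53_category == "MULTI_HIT"))))
    stopifnot(aggregates$n_samples_gt20 ==
                sum(tp53_rows$largest_cluster > 20))
  }

  report <- structure(list(
    per_sample = per_sample, aggregates = aggregates,
    errors = errors,
    chromothripsis_calls = ct_calls,
    telomere_metrics = tel_metrics,
    insertion_calls = insertions,
    provenance = list(
      n_samples = length(profiles),
      locus = locus,
      config_hash = derive_seed(0, jsonlite::toJSON(config, force = TRUE)),
      package_version = as.character(utils::packageVersion("myeloscape")))
  ), class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per_sample, file.path(out_dir, "per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      aggregates[setdiff(names(aggregates), "insertion_fisher")],
      file.path(out_dir, "aggregates.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @exportS3Method base::print
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: %d samples, %d failed>\n",
              nrow(x$per_sample), length(x$errors)))
  if (!is.null(x$aggregates$multihit_fraction)) {
    cat(sprintf("  TP53 multi-hit: %.0f%%; chromothripsis: %.0f%%; median SVs: %g\n",
                100 * x$aggregates$multihit_fraction,
                100 * x$aggregates$chromothripsis_fraction,
                x$aggregates$median_sv_count))
  }
  invisible(x)
}

#' Ground-truth recovery metrics on a simulated cohort
#'
#' Compares the classifiers' output against the generator's ground
#' truth: fraction of samples whose locus category matches the planted
#' mechanism, chromothripsis sensitivity (planted samples with a
#' high-confidence call on a planted chromosome) and specificity
#' (unplanted samples with no high-confidence call), and -- when reads
#' were generated -- the fraction of planted somatic insertion loci
#' recovered (position within `cluster_bp`) together with the number of
#' false insertion calls.
#'
#' @param sim a [simulate_cohort()] result.
#' @param locus classification locus (default the toy TP53 locus).
#' @param cluster_bp positional tolerance for insertion recovery.
#' @param thresholds allele-status thresholds.
#' @return list with `tp53_category_recovery`,
#'   `chromothripsis_sensitivity`, `chromothripsis_specificity`,
#'   `chromothripsis_fraction_high`, `insertion_recovery`,
#'   `insertion_false_calls`.
#' @export
recovery_metrics <- function(sim, locus = tp53_locus_toy(),
                             cluster_bp = 50,
                             thresholds = allele_status_thresholds()) {
  profiles <- sim$profiles
  truths <- sim$truth$samples
  n <- length(profiles)
  cat_ok <- 0L
  sens <- c(0L, 0L)  # hits, planted
  spec <- c(0L, 0L)  # clean, unplanted
  n_high <- 0L
  n_any <- 0L
  ins_found <- 0L
  ins_planted <- 0L
  ins_false <- 0L
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    tr <- truths[[i]]
    call <- classify_locus(locus, p, thresholds = thresholds)
    cat_ok <- cat_ok + (call$category == tr$tp53$category)
    ct <- call_chromothripsis(p)
    hi <- unique(ct$chrom[ct$confidence == "HIGH"])
    n_high <- n_high + (length(hi) > 0)
    n_any <- n_any + any(ct$confidence %in% c("HIGH", "LOW"))
    planted <- unique(tr$chromothripsis$chrom)
    if (length(planted)) {
      sens <- sens + c(as.integer(any(planted %in% hi)), 1L)
    } else {
      spec <- spec + c(as.integer(length(hi) == 0), 1L)
    }
    treads <- read_sample_reads(p, "tumor")
    if (!is.null(treads)) {
      calls <- detect_interstitial_insertions(
        treads, read_sample_reads(p, "normal"), svs = p$svs,
        dict = p$dict)
      planted_ins <- tr$insertions
      ins_planted <- ins_planted + nrow(planted_ins)
      for (k in seq_len(nrow(planted_ins))) {
        hit <- any(calls$chrom == planted_ins$chrom[k] &
                     abs(calls$pos - planted_ins$pos[k]) <= cluster_bp)
        ins_found <- ins_found + hit
      }
      for (k in seq_len(nrow(calls))) {
        planted_hit <- nrow(planted_ins) > 0 &&
          any(planted_ins$chrom == calls$chrom[k] &
                abs(planted_ins$pos - calls$pos[k]) <= cluster_bp)
        ins_false <- ins_false + !planted_hit
      }
    }
  }
  list(
    tp53_category_recovery = cat_ok / n,
    chromothripsis_sensitivity = if (sens[2] > 0) sens[1] / sens[2] else NA,
    chromothripsis_specificity = if (spec[2] > 0) spec[1] / spec[2] else NA,
    chromothripsis_fraction_high = n_high / n,
    chromothripsis_fraction_any = n_any / n,
    insertion_recovery = if (ins_planted > 0) ins_found / ins_planted else NA,
    insertion_false_calls = ins_false)
}

#' Oncoprint-style gene-by-sample mutation matrix
#'
#' Cell values: `multi` for two or more SNV/indel hits in the gene,
#' else `SNV`/`indel`, else `SV` for a breakend in the gene body, else
#' `CN_loss`/`CN_gain` by majority overlap, else `none`. Genes absent
#' from the annotation produce a warning and an empty row.
#'
#' @param profiles list of [sample_profile()] objects.
#' @param gene_list gene symbols (rows).
#' @param annotation gene table (`chrom, start, end, gene`), default
#'   the toy annotation.
#' @return character matrix, genes x samples.
#' @export
oncoprint_matrix <- function(profiles, gene_list,
                             annotation = toy_gene_annotation()) {
  m <- matrix("none", nrow = length(gene_list), ncol = length(profiles),
              dimnames = list(gene_list,
                              vapply(profiles, `[[`, "", "sample_id")))
  for (g in gene_list) {
    row <- annotation[annotation$gene == g, , drop = FALSE]
    if (!nrow(row)) {
      warning(sprintf("gene %s not in annotation; row left empty", g))
      next
    }
    for (j in seq_along(profiles)) {
      p <- profiles[[j]]
      sv <- p$small_variants
      hits <- sv[sv$chrom == row$chrom & sv$pos >= row$start &
                   sv$pos < row$end, , drop = FALSE]
      svs <- p$svs
      bend_in <- any(
        (svs$chrom1 == row$chrom & svs$pos1 >= row$start &
           svs$pos1 < row$end) |
          (svs$chrom2 == row$chrom & svs$pos2 >= row$start &
             svs$pos2 < row$end))
      val <- if (nrow(hits) >= 2) {
        "multi"
      } else if (nrow(hits) == 1) {
        if (is_indel(hits)) "indel" else "SNV"
      } else if (bend_in) {
        "SV"
      } else {
        st <- unit_state(p$segments, row$chrom, row$start, row$end)
        switch(st, loss = "CN_loss", gain = "CN_gain", "none")
      }
      m[g, j] <- val
    }
  }
  m
}
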