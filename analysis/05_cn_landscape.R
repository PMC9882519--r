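#!/usr/bin/env Rscript
# Stage 5: cohort copy-number landscape and minimally-deleted region.
#
# Filters to mostly-diploid samples (>=50% copy-neutral autosome, no
# whole-genome doubling), computes the gene-level gain/loss landscape,
# contrasts the two cohorts, and extracts the minimally-deleted region
# on the focal-deletion arm with its gene content.

suppressMessages(library(myeloscape))

profiles <- read_sample_sheet("results/cohort/sample_sheet.tsv",
                              dict = toy_genome())
is_tp53 <- vapply(profiles, function(p)
  startsWith(p$cohort_label, "TP53"), logical(1))
ann <- toy_gene_annotation()

kept <- Filter(is_mostly_diploid, profiles[is_tp53])
cat(sprintf("mostly-diploid filter: %d/%d TP53 samples retained\n",
            length(kept), sum(is_tp53)))
ls_tp53 <- cn_frequency_landscape(kept, ann)
ls_cbf <- cn_frequency_landscape(
  Filter(is_mostly_diploid, profiles[!is_tp53]), ann)
write.table(ls_tp53, "results/cn_landscape_tp53.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cmp <- compare_landscapes(ls_tp53, ls_cbf)
write.table(cmp, "results/cn_landscape_contrast.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top differential units:\n")
print(head(cmp[, c("gene", "loss_a", "loss_b", "delta_loss", "p_adj")], 5))

mdr <- minimal_deleted_region(profiles[is_tp53], "chrT4p",
                              annotation = ann)
cat(sprintf("minimally-deleted region: %s:%d-%d (%.2f Mb), %d supporting samples, %d genes (%s...)\n",
            mdr$interval$chrom, mdr$interval$start, mdr$interval$end,
            (mdr$interval$end - mdr$interval$start) / 1e6,
            mdr$n_supporting_samples,
            length(mdr$gene_symbols_contained),
            paste(head(mdr$gene_symbols_contained, 2), collapse = ",")))
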