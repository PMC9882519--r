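#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a 42-sample TP53-mutated AML/MDS cohort plus an 18-sample
# CBF AML comparator on the 125-Mb toy genome, at the study's planted
# composition (mechanism mix 22:11:4:4:1, 60% chromothripsis, 19 focal
# deletions over a shared 2.75-Mb core, 13 insertion-positive samples),
# and writes the full per-sample file set, sample sheet and ground
# truth under results/cohort/.

suppressMessages(library(myeloscape))

seed <- 1
out <- "results/cohort"
cfg <- sim_config(seed = seed)
cat(sprintf("simulating %d + %d samples (seed %d)...\n",
            cfg$n_tp53, cfg$n_cbf, seed))
sim <- simulate_cohort(cfg, out_dir = out)

n_ct <- sum(vapply(sim$truth$samples,
                   function(t) nrow(t$chromothripsis) > 0, logical(1)))
n_mdr <- sum(vapply(sim$truth$samples,
                    function(t) !is.null(t$mdr_loss), logical(1)))
n_ins <- sum(vapply(sim$truth$samples,
                    function(t) nrow(t$insertions) > 0, logical(1)))
cat(sprintf("planted: %d chromothripsis samples, %d focal deletions, %d insertion-positive samples\n",
            n_ct, n_mdr, n_ins))
cat(sprintf("cohort written to %s (sample_sheet.tsv, truth.json)\n", out))
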