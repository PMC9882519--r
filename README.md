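# myeloscape

Genomic-landscape analysis of **TP53-mutated myeloid malignancies**
(AML/MDS) from whole-genome sequencing call sets, for analysts who have
run somatic calling (small variants, structural-variant breakend pairs,
allele-specific copy number, heterozygous-site BAF tracks, aligned
reads) and need the downstream landscape layer:

* **TP53 allele status** — wild-type / monoallelic / multi-hit
  classification from SNVs/indels, allele-specific copy loss,
  copy-neutral LOH (detected from folded B-allele frequencies at
  neutral log2 ratio) and SV disruption, with biallelic resolution.
* **Structural-variant landscape** — class counts (DEL/DUP/INS/INV/BND),
  transitive-closure clustering into complex events, cluster-size
  summaries against the >20 / >100 member thresholds, and cohort
  breakpoint frequency in fixed 100-kb windows.
* **Chromothripsis calling** — per chromosome, from the three defining
  criteria: interleaved breakpoint clusters, oscillation between two or
  three copy-number states, and randomness of join orientations
  (exact multinomial) and breakpoint spacing (KS vs exponential).
* **Cohort copy number** — mostly-diploid / whole-genome-doubling
  filters, gene-level gain/loss landscapes, cross-cohort contrasts, and
  minimally-deleted regions.
* **Telomere analytics** — GC-matched telomere content (TRPM),
  tumour/normal ratios, singleton telomere-variant-repeat profiling
  (variant hexamers flanked by ≥3 t-type TTAGGG on each side), and
  somatic interstitial telomere-insertion detection from soft-clipped
  reads.
* **Exact inference** — two-sided Fisher's exact test with conditional
  maximum-likelihood odds ratio and exact confidence bounds on the
  noncentral hypergeometric distribution, and a tie-aware exact
  Wilcoxon rank-sum test, both written from first principles.

A fully seeded **synthetic cohort generator** (`simulate_cohort()`)
emulates every statistical structure the analyses assume — recurrent
arm losses, chromothripsis with oscillating copy number, 17p-like
CN-LOH, the published TP53 hit-mechanism mix, focal deletions sharing a
2.75-Mb core, telomeric reads with variant repeats, interstitial
insertions — with complete ground truth, so each stage is testable
without controlled-access patient data.

## Core quantities

With tumour purity ρ, a CN-LOH region shows heterozygous-site
major-allele BAF near (1+ρ)/2 at log2 ratio ≈ 0; detection requires a
maximal site window with mean folded BAF ≥ 0.5 + ρ/2 − τ_baf,
|mean log2| ≤ τ_cn and ≥ n_min sites. Two SNVs prove biallelic when
their tumour-copy fractions f = v·(ρC + 2(1−ρ))/(ρC) sum above 1
(two variants on one of two alleles can each occupy at most half the
copies). Telomere content is TRPM = telomeric reads per GC-matched
(0.48–0.52) million reads, a read being telomeric when its best frame
carries ≥ ⌈6L/100⌉ accepted hexamers.

## Worked example

```r
library(myeloscape)

# exact conditional 2x2 inference (ETV6 deletion, TP53-mutant vs
# wild-type Beat AML: 6/19 vs 4/238)
fisher_exact_2x2(6, 13, 4, 234)
#> 2x2 exact conditional test: OR = 26.01, 95% CI (5.436, 142), p = 1.258e-05

# simulate a small cohort with ground truth and run the full pipeline
cfg <- sim_config(seed = 7, n_tp53 = 6, n_cbf = 3)
sim <- simulate_cohort(cfg)
rep <- run_pipeline(sim$profiles)
rep
#> <cohort_report: 9 samples, 0 failed>
#>   TP53 multi-hit: 100%; chromothripsis: 50%; median SVs: 70

classify_locus(tp53_locus_toy(), sim$profiles[["TP53_004"]])
#> <allele_status_call TP53: MULTI_HIT (SNV+CN_LOH), biallelic=BIALLELIC>

rep$chromothripsis_calls[["TP53_004"]][, c("chrom", "n_interleaved_sv",
  "n_oscillating_segments", "orientation_p", "spacing_p", "confidence")]
#>   chrom n_interleaved_sv n_oscillating_segments orientation_p spacing_p confidence
#> 1 chrT1               30                     58         0.423     0.395       HIGH
#> 2 chrT3               30                     59         0.630     0.685       HIGH

mdr <- minimal_deleted_region(sim$profiles, "chrT4p",
                              annotation = toy_gene_annotation())
unlist(mdr$interval)
#>     chrom     start       end
#>   "chrT4"   "6e+05" "3350000"
length(mdr$gene_symbols_contained)
#> [1] 18
```

The recovered minimally-deleted region is the planted 2.75-Mb core on
chrT4p with its 18 gene bodies.

The report rows carry, per sample: TP53 category/biallelic status and
mechanisms, SV counts by class, largest complex-cluster size,
chromothripsis chromosomes, tumour/normal TRPM, and somatic
telomere-insertion counts; aggregates (multi-hit fraction,
chromothripsis fraction, burden contrasts, insertion Fisher test) are
recomputed from the rows inside the pipeline as a consistency check.

## Analysis workflow

`analysis/` holds numbered drivers that run the whole study on a
simulated cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + ground truth
Rscript analysis/02_tp53_status.R       # allele-status calls
Rscript analysis/03_sv_landscape.R      # classes, clusters, windows
Rscript analysis/04_chromothripsis.R    # per-chromosome calls
Rscript analysis/05_cn_landscape.R      # landscapes + MDR
Rscript analysis/06_telomere.R          # TRPM, TVRs, insertions
Rscript analysis/07_published_tables.R  # exact 2x2 statistics
```

The methods vignette (`vignettes/tp53-landscape-methods.Rmd`) documents
every model, threshold and generator design choice.

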