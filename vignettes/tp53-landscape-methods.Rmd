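---
title: "Methods: the TP53-mutated myeloid genomic landscape pipeline"
author: "myeloscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TP53-mutated myeloid genomic landscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myeloscape)
```

# Scope and data model

TP53-mutated AML/MDS genomes are dominated by structure: multi-hit
inactivation of the TP53 locus, pervasive aneuploidy, highly complex
rearrangement clusters, chromothripsis, recurrent focal deletions, and
altered telomere maintenance. `myeloscape` implements the analysis
layer that sits on top of somatic calling: it consumes per-sample call
sets (small variants, breakend pairs, allele-specific copy-number
segments, heterozygous-site BAF tracks, aligned reads) and produces
locus classifications, chromothripsis calls, cohort landscapes and
telomere metrics.

All coordinates inside the package are 0-based half-open; VCF and SAM
positions are converted at the boundary. Samples below a tumour-purity
floor of 0.20 are rejected at load (the cohort inclusion criterion),
overridable via `min_purity`. The reference dictionary defaults to
GRCh38 primary chromosomes and is fully overridable; the simulator uses
a 4-chromosome, 125-Mb toy genome so that whole-cohort runs take
seconds to minutes.

# Allele status at a locus

## CN-LOH detection

Copy-neutral LOH is visible as a B-allele-frequency shift at a log2
coverage ratio of 0. With tumour purity $\rho$ and one parental allele
absent, a heterozygous site's major-allele fraction is

$$ b = \frac{2\rho + (1-\rho)}{2\rho + 2(1-\rho)} = \frac{1+\rho}{2}, $$

so `detect_cnloh()` reports all maximal site windows whose mean folded
BAF ($\max(b, 1-b)$; folding avoids any need for phasing) is at least
$0.5 + \rho/2 - \tau_{baf}$, whose mean segment log2 ratio is within
$\tau_{cn}$ of 0, and which span at least $n_{min}$ sites. Defaults
($\tau_{baf} = 0.05$, $\tau_{cn} = 0.2$, $n_{min} = 20$) were chosen so
detection is insensitive to noise at purity 0.4 and above: at
$\rho = 0.4$ the BAF cutoff is 0.65, while balanced sites at depth 40
have folded mean about 0.56 and a one-copy loss sits at
$1/(2-\rho) = 0.625$ (and fails the log2 condition anyway). The
implementation is an $O(n^2)$ prefix-sum scan per chromosome and is
tested for equality against a literal brute-force evaluation of every
window.

## Classification and biallelic resolution

Mechanisms at a locus are: overlapping SNV/indel calls; segments with
rounded minor copy number 0 *and* rounded total below 2 (allele loss —
requiring the minor allele to be absent stops a subclonal coverage dip
from counting as loss of the wild-type allele); CN-LOH region overlap;
and any SV breakend inside the locus. The category lattice is
`WILD_TYPE < MONOALLELIC < MULTI_HIT`, with multi-hit requiring two
small-variant hits, or one small variant plus a copy-level mechanism,
or co-occurring copy loss and SV disruption; adding a mechanism can
never demote the category (a tested invariant).

A multi-hit call is resolved `BIALLELIC` when a small variant co-occurs
with loss/CN-LOH/disruption of the other allele, when two variants are
annotated in trans, or — for two small variants on an otherwise intact
locus — by a copy-fraction argument: the fraction of tumour copies at a
locus of copy number $C$ carrying a variant with allele fraction $v$ is

$$ f = v \cdot \frac{\rho C + 2(1-\rho)}{\rho C}. $$

Two variants confined to one of two alleles each occupy at most half of
the tumour copies, so $f_1 + f_2 \le 1$; a sum above $1 + \tau_{ccf}$
excludes the single-allele configuration. We set $\tau_{ccf} = 0$ by
default (config-exposed): the bound is already conservative because it
uses the pigeonhole limit rather than a clonality model, and clonal
heterozygous pairs sit exactly at $f_1 + f_2 = 1$, so any positive
slack simply converts true trans pairs into `UNRESOLVED`. Two clonal
variants at moderate purity (e.g. VAFs 0.30/0.25 at $\rho = 0.6$, sum
$f = 0.92$) therefore remain `UNRESOLVED`, mirroring the minority of
real multi-hit cases that short reads cannot resolve.

# Structural-variant landscape

SV classes follow the breakend-orientation convention (`+/-` DEL,
`-/+` DUP, `+/+` or `-/-` INV, cross-chromosome BND; INS records keep
their inserted sequence but cluster by locus). Complex-event clustering
is the transitive closure of "some breakend of one SV lies within
`proximity_bp` of some breakend of the other on the same chromosome";
the published analyses delegate this step to a dedicated SV-chaining
tool whose linkage distance is not printed, so the 1-Mb default here is
this package's own documented choice, and the implementation (sorted
breakend chaining + graph components, provably equivalent to all-pairs
linkage) is tested against a brute-force closure oracle. Cohort
breakpoint landscapes tile chromosomes with fixed windows (100 kb
default) and count each sample at most once per window, windowing both
breakends of every SV. Complex-burden summaries use the published
strict thresholds (events of more than 20, and more than 100, member
SVs).

# Chromothripsis calling

The three defining features — clustered breakpoints with interleaving
normal sequence, oscillation between two or three copy-number states,
and fragments rejoined in random orientation and order — are
operationalised per chromosome as:

1. **Interleaving.** Two intrachromosomal SVs interleave when their
   breakend intervals cross (neither nested nor disjoint). The largest
   connected component of the crossing relation defines the candidate
   region; its size is the interleaved count.
2. **Oscillation.** Within the region, the longest run of adjacent
   segments whose rounded total copy number alternates within a 2-state
   (or 3-state) alphabet. Rounding is half-up for determinism.
3. **Randomness.** Join orientations are tested against uniformity over
   the four classes (exact multinomial up to 20 joins, chi-squared
   beyond), and inter-breakpoint gaps against an exponential with rate
   $n/\mathrm{span}$ (Kolmogorov–Smirnov), operationalising "clustering
   with interleaving normal sequence".

`HIGH` confidence requires all of: interleaved count $\ge 6$;
oscillation run $\ge 7$ at two states, or $\ge 4$ at three states plus
an interchromosomal join into the region; and neither randomness test
rejected at $\alpha = 0.05$. These thresholds follow the published
high-confidence calling scheme for short-read WGS; since only the three
qualitative criteria are printed in the study itself, every threshold
is config-exposed. `LOW` marks regions where exactly one criterion
fails marginally (counts short by at most 2; p-values above
$\alpha/5$); by construction the two $\alpha = 0.05$ tests make roughly
8–10% of genuine events marginally fail one criterion, which is why
cohort prevalence is best read from `HIGH` + `LOW` calls while
detection benchmarks use strict `HIGH`.

# Cohort copy number

"Mostly diploid" means at least 50% of covered autosomal bases at
rounded total copy number 2 and no whole-genome doubling; WGD is called
when the major allele has copy number $\ge 2$ over more than half of
covered bases (the published figure legend names the filter but not its
rule; this base-weighted majority rule is the package's own).
Gene/bin states use majority overlap (>50% of unit bases, ties toward
neutral) so a sample counts once per unit and
$\mathrm{gain} + \mathrm{loss} \le 1$. Landscape contrasts use the
exact 2x2 test per unit with Benjamini–Hochberg adjustment at 0.05.

The minimally-deleted region of an arm is the deepest interval of the
per-sample loss-footprint coverage: equivalently, the maximal interval
contained in every supporting sample's union of losses. When the losses
share no common interval the deepest interval is returned flagged
non-universal with its supporting count.

# Telomere analytics

A read is telomeric when its best frame (six frames, both orientations;
CCCTAA-type reads are scanned through their reverse complement) carries
at least $\lceil 6L/100 \rceil$ hexamers from the accepted set — t-type
TTAGGG plus the standard ten-hexamer TVR panel (the study names only
TTTGGG; the panel is config-exposed). Telomere content is reported as
TRPM — telomeric reads per GC-content-matched million — where the
denominator counts reads whose realised GC fraction lies in
[0.48, 0.52] (telomere-like GC; the window follows the cited tooling's
convention since the study prints neither). A variant hexamer is a
*singleton* when flanked by at least three consecutive t-type hexamers
on each side within the read; singleton counting is tested against an
independent sliding-window oracle.

Interstitial telomere insertions are detected from soft-clipped reads:
clips of at least 12 bases whose hexamer content is $\ge 0.8$ telomeric
are clustered within 50 bp; a cluster with $\ge 3$ tumour reads, zero
qualifying normal reads, and a position outside the outermost 500 kb of
its chromosome (where genuine telomere repeats live) becomes a somatic
call, annotated with the nearest SV-breakend distance and a 10-kb
chromothripsis-proximity flag. None of these knobs is printed in the
study ("similar to previously described"); all are declared defaults.

# Exact statistics

The 2x2 machinery is implemented from first principles on the
noncentral hypergeometric distribution: the two-sided p sums the
probabilities of all conditional tables no more probable than the
observed one (the convention of the standard software lineage; a
doubled-one-tail rule is available by flag); the odds ratio is the
conditional MLE solving $E[a \mid \psi] = a_{obs}$; the confidence
bounds invert the exact one-sided tests at $\alpha/2$ per tail, all
root-found to $10^{-8}$ relative on the log-odds scale. Because the
roots are solved tightly, the last printed digit of a bound can differ
from legacy implementations whose root-finders stop earlier (e.g.
141.98 here versus a printed 141.9 where the legacy root leaves
$P(X \le a) = 0.02502$ rather than 0.0250000). Degenerate margins give
0 or $\infty$ with one-sided intervals, never an error. The Wilcoxon
rank-sum test enumerates the tie-aware mid-rank permutation
distribution by dynamic programming for combined $n \le 25$ and falls
back to the tie-corrected normal approximation with continuity
correction; t-tests and Benjamini–Hochberg adjustment delegate to base
R.

# The synthetic cohort generator

The generator exists so every stage can be validated against known
truth without the study's controlled-access data. It emulates the
*statistical structures* the analyses assume, not sequences: a
4-chromosome toy genome (50/40/25/10 Mb with named arms); recurrent
arm losses (defaults 0.80 on chrT1q and 0.55 on chrT2q, standing in
for 5q/7q); a 17p-like arm hosting the TP53 locus whose state is set
by the planted mechanism; focal deletions on chrT4p sharing an exact
2.75-Mb core containing 18 gene bodies (the first carrier anchors the
core exactly, so the minimally-deleted region is recoverable exactly);
chromothripsis regions with uniform breakpoints (1-kb minimum
fragment), strict 2- or 3-state oscillation, and random fragment
pairings redrawn until the chords form one interleaved cluster, with
orientations uniform over the four classes; binomial BAF noise at
depth 40; and read sets built from hexamer concatenations plus
GC-controlled background reads.

Two generator design points deserve emphasis:

* **Composition, not rates.** The emulated study is one fixed observed
  cohort, so event types are planted as exact shuffled compositions —
  the 22:11:4:4:1 mechanism mix, 60% chromothripsis, 45% focal
  deletion, and 13 insertion-positive samples carrying 19 loci of
  which 13 lie within 10 kb of an SV breakend — rather than Bernoulli
  rates, which would add binomial noise the published percentages do
  not contain. Within-sample randomness (purity, positions, BAF,
  reads) still comes from per-(sample, stage) hashed streams, so
  adding comparator samples never perturbs existing samples.
* **Burden calibration.** Complex-event sizes are pinned by the
  printed cluster composition: regular index events draw 44–190
  breakpoints (22–95 member SVs, always above the 20-member
  threshold), massive events 210–300 (always above 100), and satellite
  second events 24–80 (smaller than the index event, as real satellite
  shatterings are). With those fixed, the background simple-SV rate
  (15 per sample) was calibrated on held-out seeds so the cohort
  median SV burden sits near the published median of 71; the
  complex-SV fraction then comes out near 0.80 rather than the
  published 0.68 — the two printed burden summaries cannot both be
  matched with uniform event sizes, and the median was prioritised.
* **Exact content planting.** Telomere content is planted by counting:
  the realised number of in-window background reads fixes the number
  of emitted telomeric reads so the realised TRPM matches the target
  up to integer rounding. Recovery tests therefore check the analyser
  against the generator's realised truth read-for-read; TRPM
  granularity is $10^6/G$ for $G$ GC-matched reads (about 1,500 TRPM at
  the 4,000-read cohort default, 18 TRPM at the 150,000-read content
  scale used for the shortening analysis).

Problem sizes used throughout the analyses and tests: 42 TP53 + 18 CBF
samples (40 + 10 in the recovery suite), 4,000 background reads per
tissue in cohort runs, 150,000 reads per tissue across 8 pairs for the
telomere-shortening recomputation, and 1,000 segment-only samples for
the distributional contract on arm-loss rates.

What passing tests do *not* show about real data: the generator has no
sequencing-error model, no mappability or GC-coverage bias, no
subclonal structure, no germline contamination of somatic calls, and
its chromothripsis events are cleaner than real ones (strict
alternation, exactly uniform orientations). Recovery rates on it are
upper bounds on real-data performance; the value of the suite is
correctness of the implemented definitions, not a clinical validation.

# Known limitations

Interleaved clusters use breakend intervals only (no derivative-chain
reconstruction); the biallelic copy-fraction rule is deliberately
conservative and leaves clonal two-SNV pairs unresolved without
phasing; insertion detection requires soft-clip evidence and so
underestimates insertions shorter than `min_clip`; and the toy genome's
small arms make window-level landscapes coarser than genome-scale
data.
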