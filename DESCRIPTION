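Package: myeloscape
Title: Genomic Landscape Analysis of TP53-Mutated Myeloid Malignancies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to characterise the somatic genomic landscape of
    TP53-mutated AML/MDS from whole-genome sequencing call sets: TP53
    allele-status classification (monoallelic vs multi-hit, biallelic
    resolution), copy-neutral LOH detection from B-allele frequencies,
    complex structural-variant clustering and breakpoint landscapes,
    per-chromosome chromothripsis calling from interleaved rearrangements
    and copy-number oscillation, cohort copy-number landscapes and
    minimally-deleted regions, telomere content (GC-matched TRPM),
    singleton telomere-variant-repeat profiling and interstitial telomere
    insertion detection, plus exact conditional 2x2 inference. Ships a
    fully seeded synthetic tumour/normal cohort generator with ground
    truth so every analysis stage is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
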