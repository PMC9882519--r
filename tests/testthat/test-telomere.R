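hex_cat <- function(...) paste0(...)

test_that("hexamer-content classification follows the scaled threshold", {
  pure <- strrep("TTAGGG", 17)  # 102 bp, 17 hexamers >= ceil(6*102/100)=7
  r <- classify_telomeric_read(pure)
  expect_true(r$telomeric)
  expect_equal(r$n_accepted, 17)
  expect_equal(r$decomposition[[1]], rep("TTAGGG", 17))
  # reverse-orientation read classifies through its complement
  rc <- strrep("CCCTAA", 17)
  r2 <- classify_telomeric_read(rc)
  expect_true(r2$telomeric)
  expect_equal(r2$decomposition[[1]], rep("TTAGGG", 17))
  # a fixed random read is not telomeric
  set.seed(151)
  rnd <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  expect_false(classify_telomeric_read(rnd)$telomeric)
  # frame shift tolerated: 2 leading bases then hexamers
  shifted <- paste0("AC", strrep("TTAGGG", 16))
  expect_true(classify_telomeric_read(shifted)$telomeric)
  # non-ACGT reads are skipped with a message
  expect_message(out <- classify_telomeric_read("TTAGGGNNN"), "skipping")
  expect_true(is.na(out$telomeric))
})

test_that("TRPM is telomeric reads per GC-matched million and scale-invariant", {
  set.seed(152)
  tel <- data.frame(seq = replicate(10, strrep("TTAGGG", 17)))
  # GC-matched background: exactly half G/C
  bg_seq <- replicate(500, paste(sample(c(rep(c("G", "C"), 25),
                                          rep(c("A", "T"), 25))),
                                 collapse = ""))
  low_seq <- replicate(200, paste(sample(c(rep("G", 20), rep("A", 80))),
                                  collapse = ""))
  reads <- data.frame(seq = c(tel$seq, bg_seq, low_seq))
  m <- telomere_content(reads)
  # telomeric reads themselves sit in the GC window (GC 0.5)
  expect_equal(m$n_gc_matched_reads, 510)
  expect_equal(m$n_telomeric_reads, 10)
  expect_equal(m$trpm, 10 / 510 * 1e6)
  # duplicating every read leaves TRPM unchanged
  m2 <- telomere_content(rbind(reads, reads))
  expect_equal(m2$trpm, m$trpm)
  # an empty GC window is an error, not a silent zero
  expect_error(telomere_content(data.frame(seq = low_seq)),
               "TRPM undefined")
})

test_that("tumour/normal ratio handles the zero-normal marker", {
  mk <- function(trpm) structure(list(trpm = trpm), class = "telomere_metrics")
  r <- tumor_normal_ratio(mk(500), mk(1000))
  expect_equal(r$ratio, 0.5)
  expect_equal(r$difference, -500)
  expect_equal(tumor_normal_ratio(mk(800), mk(800))$ratio, 1)
  r0 <- tumor_normal_ratio(mk(500), mk(0))
  expect_true(is.na(r0$ratio))
  expect_equal(r0$difference, 500)
})

test_that("singleton TVRs require three t-type flanks on each side", {
  d1 <- c(rep("TTAGGG", 3), "TTTGGG", rep("TTAGGG", 3))
  expect_equal(singleton_tvr_profile(list(d1))[["TTTGGG"]], 1L)
  # adjacent variants break both flanks
  d2 <- c(rep("TTAGGG", 3), "TTTGGG", "TTTGGG", rep("TTAGGG", 3))
  expect_equal(sum(singleton_tvr_profile(list(d2))), 0L)
  # two flanking t-types are not enough
  d3 <- c(rep("TTAGGG", 2), "TTTGGG", rep("TTAGGG", 3))
  expect_equal(sum(singleton_tvr_profile(list(d3))), 0L)
})

test_that("singleton counting equals an independent sliding-window oracle", {
  oracle <- function(hex, tvr_set) {
    counts <- setNames(integer(length(tvr_set)), tvr_set)
    n <- length(hex)
    if (n >= 7) {
      for (i in 4:(n - 3)) {
        if (hex[i] %in% tvr_set &&
            all(hex[(i - 3):(i - 1)] == "TTAGGG") &&
            all(hex[(i + 1):(i + 3)] == "TTAGGG")) {
          counts[hex[i]] <- counts[hex[i]] + 1L
        }
      }
    }
    counts
  }
  set.seed(161)
  tvr <- default_tvr_set()
  for (rep in 1:25) {
    decomp <- lapply(seq_len(sample(3:10, 1)), function(i) {
      sample(c("TTAGGG", tvr), sample(4:25, 1), replace = TRUE,
             prob = c(0.8, rep(0.2 / length(tvr), length(tvr))))
    })
    mine <- singleton_tvr_profile(decomp)
    ref <- Reduce(`+`, lapply(decomp, oracle, tvr_set = tvr))
    expect_equal(mine, ref)
  }
})

test_that("requested singleton TVR rate is recovered from simulated reads", {
  set.seed(171)
  comp <- c(TTTGGG = 0.04)
  r <- simulate_telomere_reads(2000, trpm = 2e5, tvr_composition = comp,
                               frac_gc_matched = 0.5)
  m <- telomere_content(r$reads)
  # expected singletons per read: interior positions with 6 t-type flanks
  n_interior <- 17 - 6
  p_single <- comp[["TTTGGG"]] * (1 - sum(comp))^6
  expected <- m$n_telomeric_reads * n_interior * p_single
  observed <- m$singleton_tvr_counts[["TTTGGG"]]
  expect_gt(observed, expected - 3 * sqrt(expected))
  expect_lt(observed, expected + 3 * sqrt(expected))
})

test_that("planted insertions are recovered and germline loci subtracted", {
  set.seed(181)
  loci <- data.frame(chrom = c("chrT1", "chrT2"), pos = c(10e6, 7e6))
  tum <- simulate_telomere_reads(800, insertion_loci = loci,
                                 insertion_support = 5)
  nor <- simulate_telomere_reads(800)
  calls <- detect_interstitial_insertions(tum$reads, nor$reads,
                                          dict = tdict)
  expect_equal(nrow(calls), 2)
  expect_equal(sort(calls$pos), sort(loci$pos))
  expect_equal(calls$n_support_tumor, c(5L, 5L))
  expect_true(all(calls$n_support_normal == 0))
  expect_true(all(calls$clipped_telomeric_fraction >= 0.8))

  # same clipped reads present in the normal: no somatic call
  nor2 <- simulate_telomere_reads(800, insertion_loci = loci,
                                  insertion_support = 5)
  calls2 <- detect_interstitial_insertions(tum$reads, nor2$reads,
                                           dict = tdict)
  expect_equal(nrow(calls2), 0)

  # no false calls on insertion-free read sets
  none <- detect_interstitial_insertions(nor$reads, tum$reads[0, ],
                                         dict = tdict)
  expect_equal(nrow(none), 0)
})

test_that("insertion calls are annotated with SV and chromothripsis proximity", {
  set.seed(191)
  loci <- data.frame(chrom = "chrT1", pos = 10e6)
  tum <- simulate_telomere_reads(400, insertion_loci = loci)
  svs <- make_sv("near", "chrT1", 10e6 + 4000, "+", "chrT1", 12e6, "-")
  ct <- data.frame(chrom = "chrT1", start = 9.5e6, end = 10.5e6)
  calls <- detect_interstitial_insertions(
    tum$reads, NULL, svs = svs, chromothripsis_calls = ct, dict = tdict)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$nearest_sv_distance_bp, 4000)
  expect_true(calls$within_chromothripsis_10kb)
  expect_false(calls$subtracted)  # missing normal flagged un-subtracted
  # termini are masked
  edge <- simulate_telomere_reads(
    400, insertion_loci = data.frame(chrom = "chrT1", pos = 2e5))
  expect_equal(nrow(detect_interstitial_insertions(edge$reads, NULL,
                                                   dict = tdict)), 0)
})

test_that("planted telomere content is recovered exactly from the reads", {
  set.seed(201)
  for (trpm in c(1500, 3000)) {
    r <- simulate_telomere_reads(6000, trpm = trpm)
    m <- telomere_content(r$reads)
    expect_equal(m$n_telomeric_reads, r$truth$n_telomeric)
    expect_equal(m$n_gc_matched_reads, r$truth$n_gc_matched)
    expect_equal(m$trpm, r$truth$trpm)
  }
})
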