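# independent O(n^2) + BFS oracle for the interleaved-cluster count
interleaved_oracle <- function(a, b) {
  n <- length(a)
  if (n < 2) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cross <- (a[i] < a[j] && a[j] < b[i] && b[i] < b[j]) ||
      (a[j] < a[i] && a[i] < b[j] && b[j] < b[i])
    adj[i, j] <- adj[j, i] <- cross
  }
  best <- 0L
  seen <- logical(n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    if (length(comp) > 1 && length(comp) > best) best <- length(comp)
  }
  best
}

test_that("interleaving follows the crossing definition", {
  # nested intervals do not interleave
  nested <- rbind(make_sv("a", "chrT1", 10e6, "+", "chrT1", 40e6, "-"),
                  make_sv("b", "chrT1", 15e6, "+", "chrT1", 20e6, "-"))
  expect_equal(interleaved_sv_count(nested)$count, 0)
  # crossing intervals do
  cross <- rbind(make_sv("a", "chrT1", 10e6, "+", "chrT1", 30e6, "-"),
                 make_sv("b", "chrT1", 20e6, "+", "chrT1", 40e6, "-"))
  r <- interleaved_sv_count(cross)
  expect_equal(r$count, 2)
  expect_equal(r$region, c(10e6, 40e6))
})

test_that("interleaved count equals the pairwise brute-force oracle", {
  set.seed(61)
  for (i in 1:15) {
    sv <- random_svs(sample(10:50, 1))
    mine <- interleaved_sv_count(sv)$count
    expect_equal(mine, interleaved_oracle(sv$pos1, sv$pos2))
  }
})

test_that("oscillation runs match inspection and the exhaustive window oracle", {
  seg_of <- function(cn) {
    do.call(rbind, lapply(seq_along(cn), function(i) {
      seg_row("chrT1", (i - 1) * 1e5, i * 1e5, cn[i],
              ceiling(cn[i] / 2), floor(cn[i] / 2))
    }))
  }
  r <- oscillation_run(seg_of(c(2, 1, 2, 1, 2, 1, 2)))
  expect_equal(r$run_length, 7)
  expect_equal(r$n_states, 2)
  expect_equal(oscillation_run(seg_of(c(2, 2, 2)))$run_length, 1)

  # oracle: test every window explicitly
  window_oracle <- function(cn, k) {
    best <- 1L
    n <- length(cn)
    for (i in seq_len(n)) for (j in i:n) {
      w <- cn[i:j]
      if (length(w) > 1 &&
          all(diff(w) != 0) && length(unique(w)) <= k) {
        best <- max(best, length(w))
      }
    }
    best
  }
  set.seed(71)
  for (rep in 1:20) {
    cn <- sample(1:4, sample(3:20, 1), replace = TRUE)
    for (k in 2:3) {
      expect_equal(oscillation_run(seg_of(cn), max_states = k)$run_length,
                   window_oracle(cn, k))
    }
  }
})

test_that("orientation uniformity test behaves at the documented points", {
  expect_equal(orientation_randomness(c(5, 5, 5, 5)), 1)
  expect_lt(orientation_randomness(c(20, 0, 0, 0)), 0.001)
  expect_true(is.na(orientation_randomness(c(0, 0, 0, 0))))
})

test_that("exact multinomial path matches an independent enumeration", {
  oracle <- function(counts) {
    n <- sum(counts)
    obs <- dmultinom(counts, prob = rep(0.25, 4))
    grid <- expand.grid(x1 = 0:n, x2 = 0:n, x3 = 0:n)
    grid <- grid[rowSums(grid) <= n, ]
    p <- 0
    for (r in seq_len(nrow(grid))) {
      x <- c(grid$x1[r], grid$x2[r], grid$x3[r],
             n - grid$x1[r] - grid$x2[r] - grid$x3[r])
      px <- dmultinom(x, prob = rep(0.25, 4))
      if (px <= obs * (1 + 1e-7)) p <- p + px
    }
    min(1, p)
  }
  set.seed(81)
  for (i in 1:8) {
    counts <- as.vector(rmultinom(1, sample(4:15, 1), rep(0.25, 4)))
    expect_equal(orientation_randomness(counts), oracle(counts),
                 tolerance = 1e-9)
  }
})

test_that("isolated simple events and single arm losses are never called", {
  sv <- rbind(make_sv("d1", "chrT1", 5e6, "+", "chrT1", 5.5e6, "-"),
              make_sv("d2", "chrT1", 20e6, "+", "chrT1", 20.5e6, "-"),
              make_sv("d3", "chrT1", 40e6, "+", "chrT1", 40.5e6, "-"))
  p <- make_profile(svs = sv)
  calls <- call_chromothripsis(p)
  expect_true(all(calls$confidence == "NONE"))

  arm_loss <- rbind(seg_row("chrT1", 0, 20e6, 1, 1, 0),
                    seg_row("chrT1", 20e6, 50e6, 2, 1, 1))
  p2 <- make_profile(segments = rbind(
    arm_loss, diploid_segments()[-1, ]))
  expect_equal(nrow(call_chromothripsis(p2)), 0)
})

test_that("planted chromothripsis is called HIGH and the call is local", {
  set.seed(91)
  ev <- simulate_chromothripsis_event("chrT1", 25e6, 33e6, 30,
                                      min_seg = 1e3)
  seg <- splice_pieces_for_test(ev$pieces, "chrT1")
  p <- make_profile(segments = seg, svs = ev$svs)
  calls <- call_chromothripsis(p)
  expect_equal(calls$confidence[calls$chrom == "chrT1"], "HIGH")

  # adding SVs on other chromosomes never changes the chrT1 call
  extra <- rbind(make_sv("x1", "chrT2", 1e6, "+", "chrT2", 2e6, "-"),
                 make_sv("x2", "chrT4", 1e6, "-", "chrT4", 3e6, "+"))
  p2 <- make_profile(segments = seg, svs = rbind(ev$svs, extra))
  calls2 <- call_chromothripsis(p2)
  expect_equal(calls2[calls2$chrom == "chrT1", ],
               calls[calls$chrom == "chrT1", ])
})

test_that("destroying a HIGH region never resurrects a call from NONE", {
  set.seed(95)
  ev <- simulate_chromothripsis_event("chrT1", 25e6, 33e6, 24,
                                      min_seg = 1e3)
  seg <- splice_pieces_for_test(ev$pieces, "chrT1")
  order_drop <- sample(nrow(ev$svs))
  state <- "start"
  for (k in 0:(nrow(ev$svs) - 1)) {
    svs_k <- ev$svs[setdiff(seq_len(nrow(ev$svs)), order_drop[seq_len(k)]), ,
                    drop = FALSE]
    p <- make_profile(svs = svs_k, segments = seg)
    calls <- call_chromothripsis(p)
    conf <- calls$confidence[calls$chrom == "chrT1"]
    conf <- if (length(conf)) conf[1] else "NONE"
    expect_false(state == "NONE" && conf == "HIGH")
    state <- conf
  }
})

test_that("cohort recovery meets sensitivity and specificity 0.9 at defaults", {
  cfg <- sim_config(seed = 11, n_tp53 = 40, n_cbf = 0, emit_reads = FALSE)
  sim <- simulate_cohort(cfg)
  prevalence <- mean(vapply(sim$truth$samples,
                            function(t) nrow(t$chromothripsis) > 0,
                            logical(1)))
  expect_gt(prevalence, 0.4)  # 60% target rate, binomially sampled
  m <- recovery_metrics(sim)
  expect_gte(m$chromothripsis_sensitivity, 0.9)
  expect_gte(m$chromothripsis_specificity, 0.9)
})
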