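# preserved-structure assertions used across sampler tests
expect_structure_preserved <- function(orig, samp) {
  expect_s3_class(samp, "track")
  expect_equal(n_segments(samp), n_segments(orig))
  expect_equal(samp$coverage_bp, orig$coverage_bp)
  for (ch in unique(orig$chrom)) {
    so <- orig$start[orig$chrom == ch]; eo <- orig$end[orig$chrom == ch]
    ss <- samp$start[samp$chrom == ch]; es <- samp$end[samp$chrom == ch]
    expect_equal(sort(es - ss), sort(eo - so))  # length multiset
    len <- orig$genome$lengths[[ch]]
    gaps_of <- function(s, e) c(s[1], if (length(s) > 1) s[-1] - e[-length(e)],
                                len - e[length(e)])
    expect_equal(sort(gaps_of(ss, es)), sort(gaps_of(so, eo)))  # gap multiset
  }
}

test_that("per-track sampler preserves lengths, gaps, count, coverage", {
  set.seed(71)
  for (i in 1:20) {
    g <- toy_genome(n = sample(100:500, 1), chroms = sample(1:2, 1))
    t <- random_track(g, sample(1:10, 1))
    s <- sample_track_preserving_structure(t, seed = i)
    expect_structure_preserved(t, s)
  }
  g <- toy_genome(100)
  expect_error(sample_track_preserving_structure(track(g)), "empty")
})

test_that("a track covering a whole chromosome is returned unchanged", {
  g <- genome_definition(c(chr1 = 50))
  t <- track(g, "chr1", 0, 50)
  s <- sample_track_preserving_structure(t, seed = 1)
  expect_equal(s$start, 0)
  expect_equal(s$end, 50)
})

test_that("single-segment placement is uniform over permutation layouts", {
  # one segment of length 10 on a 30 bp chromosome: gaps (5, 15) permute to
  # layouts starting at 5 or 15, each with probability 1/2
  g <- genome_definition(c(chr1 = 30))
  t <- track(g, "chr1", 5, 15)
  set.seed(555)
  starts <- vapply(1:1000, function(i)
    sample_track_preserving_structure(t)$start, numeric(1))
  tab <- table(factor(starts, levels = c(5, 15)))
  expect_equal(sum(tab), 1000)
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("two-segment placement matches exhaustive layout enumeration", {
  # lengths {3, 5}, gaps {2, 4, 6} on a 20 bp chromosome: enumerate all
  # 2! * 3! joint permutations and compare sampled layout frequencies
  g <- genome_definition(c(chr1 = 20))
  t <- track(g, "chr1", c(2, 9), c(5, 14))  # lengths 3,5; gaps 2,4,6
  L <- c(3, 5); gaps <- c(2, 4, 6)
  perm3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  layouts <- character(0)
  for (lp in list(c(1, 2), c(2, 1)))
    for (gp in perm3) {
      gg <- gaps[gp]; ll <- L[lp]
      starts <- cumsum(gg[1:2]) + c(0, ll[1])
      layouts <- c(layouts, paste(starts, ll, collapse = ";"))
    }
  expected <- table(layouts) / length(layouts)
  set.seed(556)
  draws <- vapply(1:2000, function(i) {
    s <- sample_track_preserving_structure(t)
    paste(s$start, s$end - s$start, collapse = ";")
  }, character(1))
  obs <- table(factor(draws, levels = names(expected)))
  expect_equal(sum(obs), 2000)  # every draw is an enumerated layout
  expect_gt(stats::chisq.test(obs, p = as.vector(expected))$p.value, 0.01)
})

test_that("suite per-track sampling is reproducible and independent", {
  set.seed(77)
  g <- toy_genome(500)
  ts <- lapply(1:3, function(i) random_track(g, 6, label = paste0("t", i)))
  a <- sample_suite_per_track(ts, seed = 42)
  b <- sample_suite_per_track(ts, seed = 42)
  for (i in 1:3) {
    expect_equal(a[[i]]$start, b[[i]]$start)
    expect_structure_preserved(ts[[i]], a[[i]])
  }
  # independence across tracks: overlap of randomized pairs matches the
  # overlap distribution of independently randomized single tracks
  t1 <- random_track(g, 5); t2 <- random_track(g, 5)
  joint <- vapply(1:300, function(i) {
    s <- sample_suite_per_track(list(t1, t2), seed = i)
    intersect_bp(s[[1]], s[[2]])
  }, numeric(1))
  indep <- vapply(1:300, function(i) {
    a <- sample_track_preserving_structure(t1, seed = 7000 + 2 * i)
    b <- sample_track_preserving_structure(t2, seed = 9000 + 2 * i + 1)
    intersect_bp(a, b)
  }, numeric(1))
  expect_lt(abs(mean(joint) - mean(indep)),
            4 * sqrt(var(joint) / 300 + var(indep) / 300) + 1e-9)
})

test_that("pooled sampler conserves the pool and per-track counts", {
  set.seed(83)
  g <- toy_genome(400)
  ts <- lapply(1:4, function(i) random_track(g, sample(2:6, 1),
                                             label = paste0("t", i)))
  for (s in 1:10) {
    out <- sample_suite_pooled(ts, preserve_counts = TRUE,
                               replacement = FALSE, seed = s)
    expect_equal(vapply(out, function(t) t$n_elements, numeric(1)),
                 vapply(ts, n_segments, integer(1)))
    # without replacement the union of outputs covers exactly the pool bp
    all_in <- do.call(rbind, lapply(ts, function(t)
      data.frame(t$chrom, t$start, t$end)))
    all_out <- do.call(rbind, lapply(out, function(t)
      data.frame(t$chrom, t$start, t$end)))
    tin <- track(g, all_in[[1]], all_in[[2]], all_in[[3]])
    tout <- track(g, all_out[[1]], all_out[[2]], all_out[[3]])
    expect_equal(tout$chrom, tin$chrom)
    expect_equal(tout$start, tin$start)
    expect_equal(tout$end, tin$end)
  }
  # with replacement, counts preserved but segments may repeat
  out2 <- sample_suite_pooled(ts, replacement = TRUE, seed = 1)
  expect_equal(vapply(out2, function(t) t$n_elements, numeric(1)),
               vapply(ts, n_segments, integer(1)))
})

test_that("pooled sampler without count preservation keeps the total", {
  set.seed(89)
  g <- toy_genome(400)
  ts <- lapply(1:3, function(i) random_track(g, 4))
  total <- sum(vapply(ts, n_segments, integer(1)))
  out <- sample_suite_pooled(ts, preserve_counts = FALSE,
                             replacement = FALSE, seed = 5)
  expect_equal(sum(vapply(out, function(t) t$n_elements, numeric(1))), total)
})

test_that("pooled two-track overlap matches exchangeability enumeration", {
  # <= 8 segments: enumerate all equally likely partitions of the pool into
  # (track1: k1, track2: k2) and compare the expected pairwise overlap
  g <- genome_definition(c(chr1 = 60))
  t1 <- track(g, "chr1", c(0, 20), c(5, 30))        # 2 segments
  t2 <- track(g, "chr1", c(10, 40), c(15, 50))      # 2 segments
  pool <- data.frame(start = c(0, 20, 10, 40), end = c(5, 30, 15, 50))
  combos <- utils::combn(4, 2)
  exp_overlap <- mean(apply(combos, 2, function(ix) {
    a <- track(g, rep("chr1", 2), pool$start[ix], pool$end[ix])
    b <- track(g, rep("chr1", 2), pool$start[-ix], pool$end[-ix])
    intersect_bp(a, b)
  }))
  draws <- vapply(1:400, function(i) {
    out <- sample_suite_pooled(list(t1, t2), seed = i)
    intersect_bp(out[[1]], out[[2]])
  }, numeric(1))
  se <- sqrt(stats::var(draws) / length(draws))
  expect_lt(abs(mean(draws) - exp_overlap), 4 * se + 1e-9)
})

test_that("across-suite track permutation conserves the track multiset", {
  set.seed(91)
  g <- toy_genome(300)
  t1 <- lapply(1:2, function(i) random_track(g, 3, label = paste0("a", i)))
  t2 <- lapply(1:2, function(i) random_track(g, 3, label = paste0("b", i)))
  out <- sample_across_suites(t1, t2, mode = "permute-tracks", seed = 3)
  expect_equal(length(out$suite1), 2)
  expect_equal(length(out$suite2), 2)
  labs <- sort(vapply(c(out$suite1, out$suite2), function(t) t$label,
                      character(1)))
  expect_equal(labs, sort(c("a1", "a2", "b1", "b2")))
  # all tracks identical -> any permutation leaves statistics unchanged
  same <- lapply(1:2, function(i) track(g, "chr1", 0, 50))
  o2 <- sample_across_suites(same, same, mode = "permute-tracks", seed = 9)
  expect_equal(r_statistic(c(o2$suite1, o2$suite2), "jaccard"),
               r_statistic(c(same, same), "jaccard"))
})

test_that("track permutation assigns suites uniformly (chi-square)", {
  g <- toy_genome(100)
  ts <- lapply(1:4, function(i) track(g, "chr1", 10 * i, 10 * i + 5,
                                      label = paste0("t", i)))
  # which unordered pair of the 4 tracks lands in suite 1: 6 outcomes
  set.seed(557)
  draws <- vapply(1:1200, function(i) {
    o <- sample_across_suites(ts[1:2], ts[3:4], mode = "permute-tracks")
    paste(sort(vapply(o$suite1, function(t) t$label, character(1))),
          collapse = ",")
  }, character(1))
  tab <- table(draws)
  expect_equal(length(tab), 6)
  expect_gt(stats::chisq.test(tab, p = rep(1 / 6, 6))$p.value, 0.01)
})

test_that("pool-elements across suites re-splits by suite sizes", {
  set.seed(101)
  g <- toy_genome(300)
  t1 <- lapply(1:3, function(i) random_track(g, 3))
  t2 <- lapply(1:2, function(i) random_track(g, 3))
  out <- sample_across_suites(t1, t2, mode = "pool-elements", seed = 4)
  expect_equal(length(out$suite1), 3)
  expect_equal(length(out$suite2), 2)
})

test_that("samplers are deterministic given identical seeds", {
  set.seed(103)
  g <- toy_genome(500)
  ts <- lapply(1:3, function(i) random_track(g, 5))
  expect_identical(sample_suite_pooled(ts, seed = 11),
                   sample_suite_pooled(ts, seed = 11))
  expect_identical(sample_across_suites(ts[1:2], ts[3], seed = 11),
                   sample_across_suites(ts[1:2], ts[3], seed = 11))
})
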