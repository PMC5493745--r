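# brute-force Q/R by explicit double loops over ordered pairs (oracle route)
oracle_q <- function(i, tracks, stat, agg = mean) {
  f <- function(a, b) {
    o <- oracle_contingency(a, b)
    if (stat == "jaccard") oracle_jaccard(o) else oracle_forbes(o)
  }
  agg(vapply(setdiff(seq_along(tracks), i),
             function(j) f(tracks[[i]], tracks[[j]]), numeric(1)))
}
oracle_r <- function(tracks, stat) {
  mean(vapply(seq_along(tracks), function(i) oracle_q(i, tracks, stat),
              numeric(1)))
}

test_that("Q matches its printed mean form and other aggregators", {
  g <- genome_definition(c(chr1 = 1000))
  # three tracks engineered so T(1,2) and T(1,3) are known under jaccard
  t1 <- track(g, "chr1", 0, 100)
  t2 <- track(g, "chr1", 0, 100)      # J = 1
  t3 <- track(g, "chr1", 50, 150)     # J = 50/150 = 1/3
  expect_equal(q_statistic(1, list(t1, t2, t3), "jaccard", "mean"),
               mean(c(1, 1 / 3)))
  expect_equal(q_statistic(1, list(t1, t2, t3), "jaccard", "max"), 1)
  expect_equal(q_statistic(1, list(t1, t2, t3), "jaccard", "min"), 1 / 3)
  same <- list(t1, t2, track(g, "chr1", 0, 100))
  for (i in 1:3) expect_equal(q_statistic(i, same, "jaccard"), 1)
  expect_error(q_statistic(1, list(t1), "jaccard"), "at least 2")
})

test_that("R matches enumeration oracle; n = 2 collapses to T", {
  g <- genome_definition(c(chr1 = 500))
  a <- track(g, "chr1", 0, 60); b <- track(g, "chr1", 30, 90)
  expect_equal(r_statistic(list(a, b), "jaccard"),
               pairwise_T(a, b, "jaccard"))
  set.seed(97)
  for (i in 1:10) {
    gg <- toy_genome(n = 400)
    ts <- lapply(1:4, function(j) random_track(gg, 5))
    expect_equal(r_statistic(ts, "jaccard"), oracle_r(ts, "jaccard"))
    expect_equal(r_statistic(ts, "forbes"), oracle_r(ts, "forbes"))
    # order invariance
    perm <- sample(4)
    expect_equal(r_statistic(ts[perm], "forbes"),
                 r_statistic(ts, "forbes"))
  }
  ident <- lapply(1:3, function(i) track(g, "chr1", 0, 100))
  expect_equal(r_statistic(ident, "jaccard"), 1)
})

test_that("query_vs_suite ranks descending and records failures", {
  g <- genome_definition(c(chr1 = 1000))
  q <- track(g, "chr1", 0, 100, label = "query")
  refs <- list(track(g, "chr1", 0, 100, label = "match"),
               track(g, "chr1", 50, 150, label = "half"),
               track(g, "chr1", 500, 600, label = "far"))
  res <- query_vs_suite(q, refs, "jaccard")
  expect_equal(res$table$label[1], "match")
  expect_equal(res$table$value[1], 1)
  expect_equal(res$table$rank, 1:3)

  # all disjoint -> all zero, tied average ranks
  far <- list(track(g, "chr1", 500, 520, label = "a"),
              track(g, "chr1", 600, 620, label = "b"))
  res2 <- query_vs_suite(q, far, "jaccard")
  expect_equal(res2$table$value, c(0, 0))
  expect_equal(res2$table$rank, c(1.5, 1.5))

  # per-track statistic failure (empty track under forbes) is recorded
  withmissing <- c(refs, list(track(g, label = "void")))
  res3 <- query_vs_suite(q, withmissing, "forbes")
  expect_equal(names(res3$errors), "void")
  expect_equal(sum(!is.na(res3$table$value)), 3)
})

test_that("query ranking recovers the generative graded ordering", {
  g <- genome_definition(c(chr1 = 5e4))
  hits <- 0
  for (r in 1:10) {
    sp <- synthetic_suite_spec(g, 3, 0.2, "shared-signal",
                               rho = c(0.8, 0.5, 0.2),
                               query_fraction = 0.2, seed = 400 + r)
    s <- generate_suite(sp)
    res <- query_vs_suite(s$query, s$tracks, "tetrachoric")
    hits <- hits + identical(res$table$label,
                             c("track01", "track02", "track03"))
  }
  expect_gte(hits, 9)
})

test_that("cross_suite_matrix matches elementwise recomputation", {
  set.seed(19)
  g <- toy_genome(n = 400)
  t1 <- lapply(1:3, function(i) random_track(g, 5, label = paste0("a", i)))
  t2 <- lapply(1:2, function(i) random_track(g, 5, label = paste0("b", i)))
  m <- cross_suite_matrix(t1, t2, "jaccard")
  expect_equal(dim(m$values), c(3, 2))
  for (i in 1:3) for (j in 1:2) {
    o <- oracle_contingency(t1[[i]], t2[[j]])
    expect_equal(m$values[i, j], oracle_jaccard(o))
  }
  expect_equal(m$row_means, rowMeans(m$values))
  expect_equal(m$col_means, colMeans(m$values))
  # suite2 = suite1: diagonal is self-similarity (1 under jaccard)
  msame <- cross_suite_matrix(t1, t1, "jaccard")
  expect_equal(unname(diag(msame$values)), rep(1, 3))
  # 1x1 equals pairwise_T
  m11 <- cross_suite_matrix(t1[1], t2[1], "forbes")
  expect_equal(m11$values[1, 1], pairwise_T(t1[[1]], t2[[1]], "forbes"))
  # degenerate cells recorded as failures, not errors
  mfail <- cross_suite_matrix(t1, list(track(g, label = "void")), "forbes")
  expect_equal(nrow(mfail$failures), 3)
  expect_true(all(is.na(mfail$values)))
})

test_that("binned occurrence matches the bp oracle and ranks bins", {
  g <- genome_definition(c(chr1 = 100))
  bins <- bin_spec(data.frame(name = c("b1", "b2"), chrom = "chr1",
                              start = c(0, 50), end = c(50, 100)), g)
  ts <- list(track(g, "chr1", 0, 50), track(g, "chr1", 0, 50))
  tab <- binned_occurrence(ts, bins)
  expect_equal(tab$value[tab$name == "b1"], 1)
  expect_equal(tab$value[tab$name == "b2"], 0)
  expect_equal(tab$rank[tab$name == "b1"], 1)
  # one whole-genome bin equals mean genome coverage fraction
  whole <- make_bins(g, 100)
  set.seed(23)
  ts2 <- lapply(1:3, function(i) random_track(g, 4))
  tabw <- binned_occurrence(ts2, whole)
  expect_equal(tabw$value,
               mean(vapply(ts2, function(t) t$coverage_bp, numeric(1))) / g$N)
  # random instances against the oracle
  for (i in 1:10) {
    gg <- toy_genome(n = 240)
    bb <- make_bins(gg, 80)
    tt <- lapply(1:3, function(j) random_track(gg, 5))
    tab <- binned_occurrence(tt, bb)
    for (k in seq_len(nrow(tab))) {
      o <- mean(vapply(tt, function(t)
        oracle_coverage_in_bin(t, tab$chrom[k], tab$start[k], tab$end[k]),
        numeric(1)))
      expect_equal(tab$bp[k], o)
      expect_equal(tab$value[k], o / (tab$end[k] - tab$start[k]))
    }
  }
})

test_that("binned co-occurrence conditions on the bin as universe", {
  g <- genome_definition(c(chr1 = 100))
  bins <- bin_spec(data.frame(name = c("b1", "b2"), chrom = "chr1",
                              start = c(0, 50), end = c(50, 100)), g)
  # all tracks identical and present in b1 only
  ts <- list(track(g, "chr1", 10, 30), track(g, "chr1", 10, 30))
  tab <- binned_cooccurrence(ts, bins, "jaccard")
  expect_equal(tab$value[tab$name == "b1"], 1)
  expect_equal(tab$rank[tab$name == "b1"], 1)
  # b2 has no coverage: the only pair is empty-vs-empty -> jaccard 0
  expect_equal(tab$value[tab$name == "b2"], 0)

  # disjoint within the bin -> 0 under jaccard
  ts2 <- list(track(g, "chr1", 0, 10), track(g, "chr1", 20, 30))
  tab2 <- binned_cooccurrence(ts2, bins, "jaccard")
  expect_equal(tab2$value[tab2$name == "b1"], 0)

  # forbes in a bin uses the bin length as N: identical tracks covering
  # 20 of the 50 bp bin give 50/20 = 2.5
  tab3 <- binned_cooccurrence(ts, bins, "forbes")
  expect_equal(tab3$value[tab3$name == "b1"], 2.5)
  # empty-in-bin pairs are missing, not errors
  expect_equal(tab3$n_missing[tab3$name == "b2"], 1)
  expect_true(is.na(tab3$value[tab3$name == "b2"]))

  # random instances: per-pair per-bin brute force under jaccard
  set.seed(29)
  for (i in 1:8) {
    gg <- toy_genome(n = 200)
    bb <- make_bins(gg, 50)
    tt <- lapply(1:3, function(j) random_track(gg, 4))
    tab <- binned_cooccurrence(tt, bb, "jaccard")
    pairs <- utils::combn(3, 2)
    for (k in seq_len(nrow(tab))) {
      vv <- apply(pairs, 2, function(ij) {
        va <- bp_vector(tt[[ij[1]]], tab$chrom[k])[(tab$start[k] + 1):tab$end[k]]
        vb <- bp_vector(tt[[ij[2]]], tab$chrom[k])[(tab$start[k] + 1):tab$end[k]]
        if (sum(va | vb) == 0) 0 else sum(va & vb) / sum(va | vb)
      })
      expect_equal(tab$value[k], mean(vv))
    }
  }
})
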