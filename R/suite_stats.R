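#' @title Integrative statistics over suites (Q, R, S)
#' @description
#' The statistic hierarchy over a suite builds on the pairwise statistic T:
#' the per-track integrative statistic Q combines T values of one track
#' against all others (mean form: `Q_i = mean_{j != i} T(A_i, A_j)`); the
#' suite statistic R combines the Q values (mean/mean form:
#' `R = mean_i Q_i`); the cross-suite statistic S lives on the full matrix
#' of T values between two suites. Binned variants condition on a genome
#' region (the bin replaces the genome as the bp universe), and the
#' coverage-depth count is the higher-order statistic that cannot be
#' decomposed into pairwise terms.
#' @name suite-stats
NULL

.agg_fun <- function(agg) {
  agg <- match.arg(agg, c("mean", "max", "min"))
  switch(agg, mean = mean, max = max, min = min)
}

# labels for a list of tracks, uniquified
.track_labels <- function(tracks) {
  lab <- vapply(tracks, function(t) t$label, character(1))
  make.unique(lab)
}

# full symmetric pairwise matrix of T values over one suite
.pairwise_matrix <- function(tracks, stat = "forbes") {
  n <- length(tracks)
  f <- .stat_fun(stat)
  M <- matrix(NA_real_, n, n, dimnames = list(.track_labels(tracks),
                                              .track_labels(tracks)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    v <- f(contingency_table(tracks[[i]], tracks[[j]]))
    M[i, j] <- v; M[j, i] <- v
  }
  M
}

# descending ranks with average ties; output order stable by label
.rank_desc <- function(values) rank(-values, ties.method = "average")

#' Per-track integrative statistic Q
#'
#' Aggregates the pairwise statistic of track `i` against every other track
#' of the suite. With `agg = "mean"` this is
#' `Q_i = (1/(n-1)) * sum_{j != i} T(A_i, A_j)`.
#'
#' @param i index of the focal track.
#' @param tracks list of >= 2 tracks on one genome.
#' @param stat pairwise statistic name (see [pairwise_T()]).
#' @param agg aggregator: `"mean"`, `"max"` or `"min"`.
#' @return numeric Q value.
#' @export
q_statistic <- function(i, tracks, stat = "forbes", agg = "mean") {
  n <- length(tracks)
  if (n < 2) stop("Q requires at least 2 tracks")
  stopifnot(i >= 1, i <= n)
  f <- .stat_fun(stat); g <- .agg_fun(agg)
  vals <- vapply(setdiff(seq_len(n), i), function(j)
    f(contingency_table(tracks[[i]], tracks[[j]])), numeric(1))
  g(vals)
}

#' Suite statistic R
#'
#' Aggregates the per-track Q values of a suite. The mean/mean form is
#' `R = (1/n) * sum_i Q_i` with `Q_i` the mean of T over the other tracks.
#'
#' @param tracks list of >= 2 tracks on one genome.
#' @param stat pairwise statistic name.
#' @param agg_inner aggregator inside each Q.
#' @param agg_outer aggregator over the Q values.
#' @return numeric R value.
#' @export
r_statistic <- function(tracks, stat = "forbes", agg_inner = "mean",
                        agg_outer = "mean") {
  n <- length(tracks)
  if (n < 2) stop("R requires at least 2 tracks")
  gi <- .agg_fun(agg_inner); go <- .agg_fun(agg_outer)
  M <- .pairwise_matrix(tracks, stat)
  q <- vapply(seq_len(n), function(i) gi(M[i, -i]), numeric(1))
  go(q)
}

#' Rank a suite against a query track
#'
#' Computes `T(query, A_j)` for every suite track and ranks descending
#' (rank 1 = most similar to the query). Statistic failures on individual
#' tracks (e.g. Forbes on an empty track) are recorded per track instead of
#' aborting the suite.
#'
#' @param query a track on the same genome as the suite.
#' @param tracks list of >= 1 tracks.
#' @param stat pairwise statistic name.
#' @return object of class `suite_analysis_result`: a list with `table`
#'   (data.frame `label`, `value`, `rank`, ordered by rank then label),
#'   `errors` (named character vector of per-track failures), `stat_name`.
#' @export
query_vs_suite <- function(query, tracks, stat = "forbes") {
  stopifnot(length(tracks) >= 1)
  f <- .stat_fun(stat)
  labels <- .track_labels(tracks)
  vals <- rep(NA_real_, length(tracks))
  errs <- character(0)
  for (j in seq_along(tracks)) {
    v <- tryCatch(f(contingency_table(query, tracks[[j]])),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) errs[labels[j]] <- v else vals[j] <- v
  }
  ok <- !is.na(vals)
  rk <- rep(NA_real_, length(tracks))
  rk[ok] <- .rank_desc(vals[ok])
  tab <- data.frame(label = labels, value = vals, rank = rk,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank, tab$label), ]
  rownames(tab) <- NULL
  structure(list(table = tab, errors = errs, stat_name = stat),
            class = "suite_analysis_result")
}

#' @export
print.suite_analysis_result <- function(x, ...) {
  cat(sprintf("<suite_analysis_result (%s), %d tracks%s>\n", x$stat_name,
              nrow(x$table),
              if (length(x$errors)) sprintf(", %d failed", length(x$errors))
              else ""))
  print(utils::head(x$table, 10), ...)
  invisible(x)
}

#' Cross-suite statistic matrix S
#'
#' The full `n1 x n2` matrix of pairwise statistics between the tracks of
#' two suites, with row and column marginal means. Per-cell failures are
#' recorded as `NA` with reasons.
#'
#' @param tracks1,tracks2 non-empty lists of tracks on one genome.
#' @param stat pairwise statistic name.
#' @return object of class `cross_suite_matrix`: list with `values`
#'   (matrix), `row_means`, `col_means`, `failures` (data.frame), `stat_name`.
#' @export
cross_suite_matrix <- function(tracks1, tracks2, stat = "forbes") {
  stopifnot(length(tracks1) >= 1, length(tracks2) >= 1)
  f <- .stat_fun(stat)
  r <- .track_labels(tracks1); cl <- .track_labels(tracks2)
  M <- matrix(NA_real_, length(tracks1), length(tracks2),
              dimnames = list(r, cl))
  fails <- list()
  for (i in seq_along(tracks1)) for (j in seq_along(tracks2)) {
    v <- tryCatch(f(contingency_table(tracks1[[i]], tracks2[[j]])),
                  error = function(e) conditionMessage(e))
    if (is.character(v))
      fails[[length(fails) + 1]] <- data.frame(row = r[i], col = cl[j],
                                               reason = v,
                                               stringsAsFactors = FALSE)
    else M[i, j] <- v
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(row = character(), col = character(), reason = character())
  structure(list(values = M,
                 row_means = rowMeans(M, na.rm = TRUE),
                 col_means = colMeans(M, na.rm = TRUE),
                 failures = failures, stat_name = stat),
            class = "cross_suite_matrix")
}

#' @export
print.cross_suite_matrix <- function(x, ...) {
  cat(sprintf("<cross_suite_matrix (%s), %d x %d>\n", x$stat_name,
              nrow(x$values), ncol(x$values)))
  print(x$values, ...)
  invisible(x)
}

#' Binned occurrence of a suite
#'
#' For every bin, aggregates the per-track coverage fraction within the bin
#' (coverage bp divided by bin length) and ranks the bins descending.
#'
#' @param tracks non-empty list of tracks.
#' @param bins a [bin_spec()].
#' @param agg aggregator over tracks within a bin.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `value` (aggregated fraction), `bp` (aggregated raw bp), `rank`.
#' @export
binned_occurrence <- function(tracks, bins, agg = "mean") {
  stopifnot(inherits(bins, "bin_spec"), length(tracks) >= 1)
  g <- .agg_fun(agg)
  b <- bins$bins
  vals <- numeric(nrow(b)); raw <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    cov <- vapply(tracks, coverage_in_bin, numeric(1),
                  chrom = b$chrom[k], start = b$start[k], end = b$end[k])
    vals[k] <- g(cov / (b$end[k] - b$start[k]))
    raw[k] <- g(cov)
  }
  out <- data.frame(b, value = vals, bp = raw,
                    rank = .rank_desc(vals), stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$name), ]
  rownames(out) <- NULL
  out
}

#' Binned co-occurrence of a suite
#'
#' For every bin, computes the chosen pairwise statistic for all unordered
#' track pairs with the bin as the bp universe (the bin length replaces the
#' genome size N) and aggregates over the pairs. Pairs with degenerate
#' margins inside a bin (e.g. a track empty in the bin, for Forbes or
#' tetrachoric) are recorded as missing for that bin, not errors; a bin
#' where every pair is missing gets value `NA`.
#'
#' @param tracks list of >= 2 tracks.
#' @param bins a [bin_spec()].
#' @param stat pairwise statistic name.
#' @param agg aggregator over the pairs within a bin.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `value`, `n_pairs`, `n_missing`, `rank` (NA values ranked last).
#' @export
binned_cooccurrence <- function(tracks, bins, stat = "jaccard",
                                agg = "mean") {
  stopifnot(inherits(bins, "bin_spec"), length(tracks) >= 2)
  f <- .stat_fun(stat); g <- .agg_fun(agg)
  b <- bins$bins
  n <- length(tracks)
  pairs <- utils::combn(n, 2)
  vals <- numeric(nrow(b)); nmiss <- integer(nrow(b))
  for (k in seq_len(nrow(b))) {
    ulen <- b$end[k] - b$start[k]
    clipped <- lapply(tracks, clip_track, chrom = b$chrom[k],
                      start = b$start[k], end = b$end[k])
    pv <- apply(pairs, 2, function(ij) {
      tryCatch(suppressWarnings(
        f(contingency_table(clipped[[ij[1]]], clipped[[ij[2]]],
                            universe_bp = ulen))),
        error = function(e) NA_real_)
    })
    nmiss[k] <- sum(is.na(pv))
    vals[k] <- if (all(is.na(pv))) NA_real_ else g(pv[!is.na(pv)])
  }
  rk <- rep(NA_real_, nrow(b))
  ok <- !is.na(vals)
  rk[ok] <- .rank_desc(vals[ok])
  rk[!ok] <- max(rk[ok], 0) + seq_len(sum(!ok))
  out <- data.frame(b, value = vals, n_pairs = ncol(pairs),
                    n_missing = nmiss, rank = rk, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$name), ]
  rownames(out) <- NULL
  out
}
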