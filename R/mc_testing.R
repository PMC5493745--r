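#' @title Monte Carlo hypothesis testing
#' @description
#' A Monte Carlo test draws `m` datasets from a null model, computes the
#' test statistic on each, and reports the add-one p-value
#' `p = (k + 1) / (m + 1)` where `k` counts null statistics at least as
#' extreme as the observed one. The estimator is strictly positive
#' (smallest attainable p is `1/(m+1)`), which is the honest resolution of
#' a finite simulation. "At least as extreme" is `>=` for the greater
#' alternative, `<=` for less, and `|x - c| >= |obs - c|` with `c` the null
#' mean for two-sided. Every result records the sampler used and a
#' multiplicity class: if either the test statistic spans tracks of the
#' suite or the sampler draws elements across tracks, p-values are at the
#' integrative multiplicity level; otherwise they are contrasting
#' (comparable per-track values).
#' @name mc-testing
NULL

.mc_p_value <- function(observed, null_values, alternative) {
  m <- length(null_values)
  k <- switch(alternative,
              greater = sum(null_values >= observed),
              less = sum(null_values <= observed),
              `two-sided` = {
                ctr <- mean(null_values)
                sum(abs(null_values - ctr) >= abs(observed - ctr))
              })
  (k + 1) / (m + 1)
}

.multiplicity_class <- function(stat_spans_tracks, sampler_spans_tracks,
                                higher_order = FALSE) {
  if (higher_order) return("higher-order")
  if (stat_spans_tracks || sampler_spans_tracks) "integrative"
  else "contrasting"
}

.new_mc_result <- function(observed, null_values, alternative, sampler,
                           multiplicity, label = NULL) {
  structure(list(observed = observed, null_values = null_values,
                 p_value = .mc_p_value(observed, null_values, alternative),
                 alternative = alternative, m = length(null_values),
                 sampler = sampler, multiplicity = multiplicity,
                 label = label, adjusted_p = NULL),
            class = "mc_test_result")
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat(sprintf(
    "<mc_test_result%s: observed = %.4g, p = %.4g (%s, m = %d, %s)>\n",
    if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
    x$observed, x$p_value, x$alternative, x$m, x$multiplicity))
  invisible(x)
}

#' Generic Monte Carlo test
#'
#' @param data the observed dataset (any object the statistic and sampler
#'   understand, e.g. a list of tracks).
#' @param statistic function `data -> numeric scalar`.
#' @param sampler function `(data, seed) -> null dataset`.
#' @param m number of null samples (>= 1).
#' @param alternative `"greater"`, `"less"` or `"two-sided"`.
#' @param seed master integer seed; null sample `i` uses a sub-seed derived
#'   from it, so identical seeds give identical results.
#' @param sampler_info a [sampler_spec()] recorded in the result.
#' @param multiplicity multiplicity class recorded in the result.
#' @return an `mc_test_result` with fields `observed`, `null_values`,
#'   `p_value`, `alternative`, `m`, `sampler`, `multiplicity`.
#' @details A statistic failure on a null sample is redrawn once (with a
#'   fresh derived seed); a second failure aborts with diagnostics, so a
#'   silently biased null distribution is impossible.
#' @export
monte_carlo_test <- function(data, statistic, sampler, m = 99,
                             alternative = c("greater", "less", "two-sided"),
                             seed = NULL, sampler_info = NULL,
                             multiplicity = "integrative") {
  alternative <- match.arg(alternative)
  stopifnot(m >= 1)
  observed <- statistic(data)
  if (!is.numeric(observed) || length(observed) != 1 || !is.finite(observed))
    stop("statistic must return a single finite number on the observed data")
  null_values <- numeric(m)
  for (i in seq_len(m)) {
    v <- tryCatch(statistic(sampler(data, .mix_seed(seed, i))),
                  error = function(e) e)
    if (inherits(v, "error")) {
      v <- tryCatch(statistic(sampler(data, .mix_seed(seed, m + i))),
                    error = function(e)
                      stop("statistic failed twice on null sample ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    }
    null_values[i] <- v
  }
  if (is.null(sampler_info))
    sampler_info <- sampler_spec("per-track", seed = seed)
  .new_mc_result(observed, null_values, alternative, sampler_info,
                 multiplicity)
}

#' Benjamini-Hochberg adjustment of Monte Carlo p-values
#'
#' Step-up false-discovery-rate adjustment across the tracks, bins or cells
#' of one analysis invocation. Input p-values must lie in (0, 1] (Monte
#' Carlo p-values are never exactly 0).
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param method only `"benjamini-hochberg"`.
#' @return adjusted p-values, monotone and `<= 1`.
#' @export
adjust_p_values <- function(p, method = "benjamini-hochberg") {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-track query test
#'
#' Tests, for each track of the suite, whether it co-occurs with a separate
#' query track more than expected by chance. The null model randomizes the
#' query track only (structure-preserving per-track sampler), keeping the
#' suite fixed; all per-track statistics are recomputed on each null draw,
#' so the per-track null distributions share the same query randomizations.
#'
#' Uncentered statistic: `T(query, A_i)` (contrasting multiplicity).
#' Centered: `T(query, A_i) - mean_j T(query, A_j)`, i.e. similarity of the
#' track relative to the suite average (integrative multiplicity, since the
#' suite mean enters every per-track value; the centered values sum to zero
#' across the suite in every sample).
#'
#' @param query a non-empty track.
#' @param tracks list of suite tracks (>= 2 when `centered`).
#' @param stat pairwise statistic name.
#' @param centered subtract the suite mean (default FALSE).
#' @param m number of null samples.
#' @param alternative test direction (default `"greater"`).
#' @param seed master seed.
#' @return object of class `per_track_mc`: list with `table` (data.frame
#'   `label`, `observed`, `p`, `p_adjusted`, `rank`), `results` (list of
#'   `mc_test_result`), `multiplicity`, `sampler`.
#' @export
per_track_query_test <- function(query, tracks, stat = "forbes",
                                 centered = FALSE, m = 99,
                                 alternative = "greater", seed = NULL) {
  n <- length(tracks)
  if (centered && n < 2) stop("centered statistic requires >= 2 tracks")
  stopifnot(n >= 1)
  f <- .stat_fun(stat)
  labels <- .track_labels(tracks)
  tvec <- function(q) vapply(tracks, function(tr)
    f(contingency_table(q, tr)), numeric(1))
  obs <- tvec(query)
  if (centered) obs <- obs - mean(obs)
  null_mat <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    qs <- sample_track_preserving_structure(query, .mix_seed(seed, i))
    v <- tvec(qs)
    null_mat[i, ] <- if (centered) v - mean(v) else v
  }
  sp <- sampler_spec("per-track",
                     variant = list(target = "query-only"),
                     preserve = c("segment count", "length multiset",
                                  "gap multiset", "coverage_bp"),
                     seed = seed)
  mult <- .multiplicity_class(stat_spans_tracks = centered,
                              sampler_spans_tracks = FALSE)
  results <- lapply(seq_len(n), function(j)
    .new_mc_result(obs[j], null_mat[, j], alternative, sp, mult,
                   label = labels[j]))
  p <- vapply(results, function(r) r$p_value, numeric(1))
  tab <- data.frame(label = labels, observed = obs, p = p,
                    p_adjusted = adjust_p_values(p),
                    rank = .rank_desc(obs), stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank, tab$label), ]
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, multiplicity = mult,
                 sampler = sp, stat_name = stat, centered = centered),
            class = "per_track_mc")
}

#' @export
print.per_track_mc <- function(x, ...) {
  cat(sprintf("<per_track_mc (%s%s), %d tracks, %s multiplicity>\n",
              x$stat_name, if (x$centered) ", centered" else "",
              nrow(x$table), x$multiplicity))
  print(utils::head(x$table, 10), ...)
  invisible(x)
}

#' Suite coherence test
#'
#' Tests whether the tracks of a suite as a whole are more similar to each
#' other than expected by chance. Test statistic: the suite statistic R
#' (mean/mean form); null model: independent structure-preserving
#' randomization of every track; greater alternative.
#'
#' @param tracks list of >= 2 non-empty tracks.
#' @param stat pairwise statistic name.
#' @param m number of null samples.
#' @param seed master seed.
#' @return an `mc_test_result`.
#' @export
suite_coherence_test <- function(tracks, stat = "forbes", m = 99,
                                 seed = NULL) {
  stopifnot(length(tracks) >= 2)
  sp <- sampler_spec("per-track",
                     preserve = c("segment count", "length multiset",
                                  "gap multiset", "coverage_bp"),
                     seed = seed)
  monte_carlo_test(
    tracks,
    statistic = function(ts) r_statistic(ts, stat = stat),
    sampler = function(ts, s) sample_suite_per_track(ts, seed = s),
    m = m, alternative = "greater", seed = seed, sampler_info = sp,
    multiplicity = .multiplicity_class(TRUE, FALSE))
}

#' Binned variation test
#'
#' Suite-level question: does per-bin occurrence (or co-occurrence) vary
#' between bins more than expected by chance? Test statistic: the variance
#' across bins of the per-bin aggregated value. Per-bin question: is the
#' value in this bin higher than expected? Per-bin statistic: the bin's
#' aggregated value. The null randomizes every track genome-wide
#' (structure-preserving per-track sampler), so the per-bin tests are
#' conditional on the suite's genome-wide coverage and co-occurrence
#' propensities.
#'
#' @param tracks list of non-empty tracks (>= 2 for co-occurrence mode).
#' @param bins a [bin_spec()] with >= 2 bins.
#' @param mode `"occurrence"` or `"cooccurrence"`.
#' @param stat pairwise statistic for co-occurrence mode.
#' @param agg aggregator within bins.
#' @param m number of null samples.
#' @param seed master seed.
#' @return list of class `binned_mc`: `suite` (an `mc_test_result` for the
#'   variance statistic), `per_bin` (data.frame `name`, `observed`, `p`,
#'   `p_adjusted`), `multiplicity`.
#' @export
binned_variation_test <- function(tracks, bins,
                                  mode = c("occurrence", "cooccurrence"),
                                  stat = "jaccard", agg = "mean", m = 99,
                                  seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(bins, "bin_spec"), nrow(bins$bins) >= 2)
  if (mode == "cooccurrence") stopifnot(length(tracks) >= 2)
  bin_values <- function(ts) {
    tab <- if (mode == "occurrence") binned_occurrence(ts, bins, agg = agg)
    else binned_cooccurrence(ts, bins, stat = stat, agg = agg)
    tab$value[match(bins$bins$name, tab$name)]
  }
  obs <- bin_values(tracks)
  null_mat <- matrix(NA_real_, m, length(obs))
  for (i in seq_len(m)) {
    ts <- sample_suite_per_track(tracks, seed = .mix_seed(seed, i))
    null_mat[i, ] <- bin_values(ts)
  }
  var_na <- function(v) stats::var(v[!is.na(v)])
  sp <- sampler_spec("per-track",
                     preserve = c("segment count", "length multiset",
                                  "gap multiset", "coverage_bp"),
                     seed = seed)
  mult <- .multiplicity_class(mode == "cooccurrence", FALSE)
  suite_res <- .new_mc_result(var_na(obs), apply(null_mat, 1, var_na),
                              "greater", sp, mult,
                              label = paste0("between-bin variance (", mode,
                                             ")"))
  p <- vapply(seq_along(obs), function(b) {
    nb <- null_mat[, b]
    if (is.na(obs[b])) return(NA_real_)
    .mc_p_value(obs[b], nb[!is.na(nb)], "greater")
  }, numeric(1))
  ok <- !is.na(p)
  padj <- rep(NA_real_, length(p))
  padj[ok] <- adjust_p_values(p[ok])
  per_bin <- data.frame(name = bins$bins$name, observed = obs, p = p,
                        p_adjusted = padj, stringsAsFactors = FALSE)
  structure(list(suite = suite_res, per_bin = per_bin, multiplicity = mult,
                 mode = mode, sampler = sp),
            class = "binned_mc")
}

#' @export
print.binned_mc <- function(x, ...) {
  cat(sprintf("<binned_mc (%s)>\n  suite-level: ", x$mode))
  print(x$suite)
  print(utils::head(x$per_bin, 10), ...)
  invisible(x)
}

# double-centered matrix: cell minus row mean minus col mean plus grand mean
.double_center <- function(M) {
  sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
}

#' Cross-suite association test
#'
#' Per-cell question: does track i of suite 1 co-occur with track j of
#' suite 2 more than expected, given each track's general propensity to
#' co-occur with tracks of the other suite? The per-cell statistic is the
#' double-centered matrix entry `T_ij - rowmean_i - colmean_j + grandmean`
#' when `cell_normalized` (the centered values sum to zero over the
#' matrix), else the raw T. Suite-pair question: does the distribution of
#' co-occurrence values have more extreme values than expected? Statistic:
#' the maximum absolute normalized cell value. Null model: whole tracks
#' permuted between the two suites (suites must be exchangeable under the
#' null).
#'
#' @param tracks1,tracks2 lists of tracks (>= 2 each for normalized mode).
#' @param stat pairwise statistic name.
#' @param cell_normalized double-center the matrix (default TRUE).
#' @param m number of null samples.
#' @param alternative per-cell test direction (default `"greater"`).
#' @param seed master seed.
#' @return list of class `cross_suite_mc`: `suite_pair` (an
#'   `mc_test_result`), `cell_p` and `cell_p_adjusted` (matrices),
#'   `observed` (the per-cell statistic matrix), `multiplicity`.
#' @export
cross_suite_test <- function(tracks1, tracks2, stat = "forbes",
                             cell_normalized = TRUE, m = 99,
                             alternative = "greater", seed = NULL) {
  if (cell_normalized)
    stopifnot(length(tracks1) >= 2, length(tracks2) >= 2)
  cell_stat <- function(t1, t2) {
    M <- cross_suite_matrix(t1, t2, stat = stat)$values
    if (anyNA(M)) stop("pairwise statistic failed on a cell")
    if (cell_normalized) .double_center(M) else M
  }
  obs <- cell_stat(tracks1, tracks2)
  n1 <- length(tracks1); n2 <- length(tracks2)
  null_arr <- array(NA_real_, c(m, n1, n2))
  null_max <- numeric(m)
  for (i in seq_len(m)) {
    sp_i <- sample_across_suites(tracks1, tracks2, mode = "permute-tracks",
                                 seed = .mix_seed(seed, i))
    Mi <- cell_stat(sp_i$suite1, sp_i$suite2)
    null_arr[i, , ] <- Mi
    null_max[i] <- max(abs(Mi))
  }
  sp <- sampler_spec("across-suites",
                     variant = list(mode = "permute-tracks"),
                     preserve = c("track multiset", "suite sizes"),
                     seed = seed)
  mult <- .multiplicity_class(TRUE, TRUE)
  suite_pair <- .new_mc_result(max(abs(obs)), null_max, "greater", sp, mult,
                               label = "max |normalized cell|")
  cell_p <- matrix(NA_real_, n1, n2, dimnames = dimnames(obs))
  for (i in seq_len(n1)) for (j in seq_len(n2))
    cell_p[i, j] <- .mc_p_value(obs[i, j], null_arr[, i, j], alternative)
  cell_padj <- matrix(adjust_p_values(as.vector(cell_p)), n1, n2,
                      dimnames = dimnames(obs))
  structure(list(suite_pair = suite_pair, cell_p = cell_p,
                 cell_p_adjusted = cell_padj, observed = obs,
                 multiplicity = mult, sampler = sp, stat_name = stat),
            class = "cross_suite_mc")
}

#' @export
print.cross_suite_mc <- function(x, ...) {
  cat(sprintf("<cross_suite_mc (%s), %d x %d cells>\n  suite-pair: ",
              x$stat_name, nrow(x$cell_p), ncol(x$cell_p)))
  print(x$suite_pair)
  invisible(x)
}
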