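#' @title Five canonical analyses of track collections
#' @description
#' End-to-end analyses for the five canonical questions on track
#' collections, composing the descriptive statistics with the optional
#' Monte Carlo tests:
#' * q1: which tracks are most representative / most atypical for the suite?
#' * q2: which tracks coincide most strongly with a separate query track?
#' * q3: do tracks of one suite coincide strongly with tracks of another?
#' * q4: in which genome regions (bins) does the suite occur the most?
#' * q5: in which bins does the suite co-occur the most?
#'
#' The default statistic is Forbes for ranking analyses. The tetrachoric
#' correlation is recommended for suites whose tracks differ strongly in
#' size; the Jaccard index is size-confounded and not recommended for
#' ranking. Tests are opt-in (`with_tests`) because Monte Carlo sampling
#' dominates runtime. Every result carries its multiplicity class and full
#' analysis provenance.
#' @name questions
NULL

.new_question_result <- function(question, table, tests, spec, multiplicity,
                                 extra = list()) {
  structure(c(list(question = question, table = table, tests = tests,
                   spec = spec, multiplicity = multiplicity), extra),
            class = "question_result")
}

#' @export
print.question_result <- function(x, ...) {
  cat(sprintf("<question_result %s (%s multiplicity)>\n", x$question,
              x$multiplicity))
  if (is.data.frame(x$table)) print(utils::head(x$table, 10), ...)
  if (length(x$tests) > 0)
    for (nm in names(x$tests)) {
      cat(" test '", nm, "': ", sep = "")
      tp <- x$tests[[nm]]
      if (inherits(tp, "mc_test_result")) print(tp) else cat("\n")
    }
  invisible(x)
}

.spec_record <- function(question, stat, agg = "mean", m = NA, seed = NULL,
                         with_tests = FALSE, extra = list()) {
  c(list(question = question, stat = stat, agg = agg, m = m,
         seed = if (is.null(seed)) NA else seed, with_tests = with_tests),
    extra)
}

#' q1: most representative and most atypical tracks of a suite
#'
#' Ranks the tracks by their per-track integrative statistic Q (aggregated
#' co-occurrence against all other tracks); rank 1 is the most
#' representative track, the last rank the most atypical (outlier
#' candidate). With `with_tests`, runs the suite coherence test ("are the
#' tracks as a whole more similar than expected by chance?") and a
#' most-representative-track test (statistic `max_i Q_i`, null =
#' independent per-track randomization: is the most representative track
#' more similar to the rest than any track would be by chance?).
#'
#' @param tracks list of >= 3 tracks (>= 2 tolerated; ranking is then
#'   degenerate by symmetry).
#' @param stat pairwise statistic name.
#' @param agg aggregator inside Q.
#' @param with_tests run the Monte Carlo tests.
#' @param m,seed Monte Carlo parameters.
#' @return a `question_result` with `table` columns `label`, `q_value`,
#'   `rank`.
#' @export
run_q1_representative <- function(tracks, stat = "forbes", agg = "mean",
                                  with_tests = FALSE, m = 99, seed = NULL) {
  n <- length(tracks)
  if (n < 2) stop("q1 requires at least 2 tracks")
  M <- .pairwise_matrix(tracks, stat)
  gi <- .agg_fun(agg)
  q <- vapply(seq_len(n), function(i) gi(M[i, -i]), numeric(1))
  tab <- data.frame(label = rownames(M), q_value = q, rank = .rank_desc(q),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank, tab$label), ]
  rownames(tab) <- NULL
  tests <- list()
  if (with_tests) {
    tests$suite_coherence <- suite_coherence_test(tracks, stat = stat,
                                                  m = m, seed = seed)
    sp <- sampler_spec("per-track",
                       preserve = c("segment count", "length multiset",
                                    "gap multiset", "coverage_bp"),
                       seed = .mix_seed(seed, 7919))
    tests$max_q <- monte_carlo_test(
      tracks,
      statistic = function(ts) {
        Mi <- .pairwise_matrix(ts, stat)
        max(vapply(seq_len(n), function(i) gi(Mi[i, -i]), numeric(1)))
      },
      sampler = function(ts, s) sample_suite_per_track(ts, seed = s),
      m = m, alternative = "greater", seed = .mix_seed(seed, 7919),
      sampler_info = sp, multiplicity = "integrative")
  }
  .new_question_result("q1-representative", tab, tests,
                       .spec_record("q1-representative", stat, agg, m, seed,
                                    with_tests),
                       multiplicity = "integrative")
}

#' q2: rank a suite against a separate query track
#'
#' Ranks the suite tracks by co-occurrence with the query. With
#' `with_tests`, runs the per-track query test in both variants (uncentered
#' = contrasting multiplicity; centered on the suite average = integrative)
#' and a suite-level test of "do the tracks as a whole coincide with the
#' query?" (statistic = mean of `T(query, A_j)` over the suite, null =
#' structure-preserving randomization of the query).
#'
#' @param tracks suite track list (n >= 1).
#' @param query a separate non-empty track.
#' @inheritParams run_q1_representative
#' @return a `question_result`; `table` columns `label`, `value`, `rank`.
#' @export
run_q2_rank_vs_query <- function(tracks, query, stat = "forbes",
                                 with_tests = FALSE, m = 99, seed = NULL) {
  desc <- query_vs_suite(query, tracks, stat = stat)
  tests <- list()
  if (with_tests) {
    tests$per_track <- per_track_query_test(query, tracks, stat = stat,
                                            centered = FALSE, m = m,
                                            seed = seed)
    if (length(tracks) >= 2)
      tests$per_track_centered <- per_track_query_test(
        query, tracks, stat = stat, centered = TRUE, m = m,
        seed = .mix_seed(seed, 104729))
    f <- .stat_fun(stat)
    sp <- sampler_spec("per-track",
                       variant = list(target = "query-only"),
                       preserve = c("segment count", "length multiset",
                                    "gap multiset", "coverage_bp"),
                       seed = .mix_seed(seed, 1299709))
    tests$suite_mean <- monte_carlo_test(
      query,
      statistic = function(q) mean(vapply(tracks, function(tr)
        f(contingency_table(q, tr)), numeric(1))),
      sampler = function(q, s) sample_track_preserving_structure(q, seed = s),
      m = m, alternative = "greater", seed = .mix_seed(seed, 1299709),
      sampler_info = sp, multiplicity = "integrative")
  }
  .new_question_result("q2-rank-vs-query", desc$table, tests,
                       .spec_record("q2-rank-vs-query", stat, m = m,
                                    seed = seed, with_tests = with_tests),
                       multiplicity = "contrasting",
                       extra = list(errors = desc$errors))
}

#' q3: cross-suite co-occurrence matrix
#'
#' The full matrix of pairwise statistics between two suites (the heatmap
#' of co-occurrence for all combinations), with the optional cross-suite
#' permutation test.
#'
#' @param tracks1,tracks2 non-empty track lists on one genome.
#' @inheritParams run_q1_representative
#' @return a `question_result`; `table` is a long-format data.frame
#'   (`row`, `col`, `value`) and the matrix is in `matrix`.
#' @export
run_q3_cross_suite <- function(tracks1, tracks2, stat = "forbes",
                               with_tests = FALSE, m = 99, seed = NULL) {
  mat <- cross_suite_matrix(tracks1, tracks2, stat = stat)
  long <- data.frame(row = rep(rownames(mat$values), ncol(mat$values)),
                     col = rep(colnames(mat$values),
                               each = nrow(mat$values)),
                     value = as.vector(mat$values),
                     stringsAsFactors = FALSE)
  tests <- list()
  if (with_tests)
    tests$cross_suite <- cross_suite_test(tracks1, tracks2, stat = stat,
                                          m = m, seed = seed)
  .new_question_result("q3-cross-suite", long, tests,
                       .spec_record("q3-cross-suite", stat, m = m,
                                    seed = seed, with_tests = with_tests),
                       multiplicity = "integrative",
                       extra = list(matrix = mat))
}

#' q4: bins with the most suite occurrences
#'
#' Ranks genome bins by aggregated track coverage (e.g. genes by the
#' frequency of somatic variants across patients, with genes as bins).
#' With `with_tests`, runs the binned variation test in occurrence mode:
#' suite-level "does occurrence vary between bins more than expected?" and
#' per-bin "is coverage in this bin higher than expected from genome-wide
#' propensities?".
#'
#' @param tracks non-empty track list.
#' @param bins a [bin_spec()].
#' @param agg aggregator over tracks in a bin.
#' @inheritParams run_q1_representative
#' @return a `question_result`; `table` from [binned_occurrence()], merged
#'   with per-bin p-values when tested.
#' @export
run_q4_binned_occurrence <- function(tracks, bins, agg = "mean",
                                     with_tests = FALSE, m = 99,
                                     seed = NULL) {
  tab <- binned_occurrence(tracks, bins, agg = agg)
  tests <- list()
  if (with_tests) {
    bt <- binned_variation_test(tracks, bins, mode = "occurrence",
                                agg = agg, m = m, seed = seed)
    tests$binned_variation <- bt$suite
    tab <- merge(tab, bt$per_bin[, c("name", "p", "p_adjusted")],
                 by = "name", sort = FALSE)
    tab <- tab[order(tab$rank, tab$name), ]
    rownames(tab) <- NULL
  }
  .new_question_result("q4-binned-occurrence", tab, tests,
                       .spec_record("q4-binned-occurrence", stat = NA,
                                    agg = agg, m = m, seed = seed,
                                    with_tests = with_tests),
                       multiplicity = "integrative")
}

#' q5: bins with the strongest suite co-occurrence
#'
#' Ranks genome bins by aggregated pairwise co-occurrence of the suite
#' within the bin (bin length as the bp universe). With `with_tests`, runs
#' the binned variation test in co-occurrence mode; because the null
#' randomizes tracks genome-wide, per-bin p-values are conditional on the
#' suite's general propensity to co-occur across the genome.
#'
#' @param tracks track list (n >= 2).
#' @param bins a [bin_spec()].
#' @param stat pairwise statistic used within bins.
#' @param agg aggregator over pairs in a bin.
#' @inheritParams run_q1_representative
#' @return a `question_result`; `table` from [binned_cooccurrence()],
#'   merged with per-bin p-values when tested.
#' @export
run_q5_binned_cooccurrence <- function(tracks, bins, stat = "jaccard",
                                       agg = "mean", with_tests = FALSE,
                                       m = 99, seed = NULL) {
  stopifnot(length(tracks) >= 2)
  tab <- binned_cooccurrence(tracks, bins, stat = stat, agg = agg)
  tests <- list()
  if (with_tests) {
    bt <- binned_variation_test(tracks, bins, mode = "cooccurrence",
                                stat = stat, agg = agg, m = m, seed = seed)
    tests$binned_variation <- bt$suite
    tab <- merge(tab, bt$per_bin[, c("name", "p", "p_adjusted")],
                 by = "name", sort = FALSE)
    tab <- tab[order(tab$rank, tab$name), ]
    rownames(tab) <- NULL
  }
  .new_question_result("q5-binned-cooccurrence", tab, tests,
                       .spec_record("q5-binned-cooccurrence", stat,
                                    agg = agg, m = m, seed = seed,
                                    with_tests = with_tests),
                       multiplicity = "integrative")
}

#' Trivial per-track descriptors
#'
#' One row per track with independent descriptors (segment count after
#' merging, original element count, coverage bp, mean merged segment
#' length). The values are neither compared nor integrated across tracks:
#' no ranking, no tests (trivial multiplicity).
#'
#' @param tracks list of tracks.
#' @return data.frame with columns `label`, `n_segments`, `n_elements`,
#'   `coverage_bp`, `mean_segment_length`.
#' @export
run_trivial_multiplicity <- function(tracks) {
  data.frame(
    label = .track_labels(tracks),
    n_segments = vapply(tracks, n_segments, integer(1)),
    n_elements = vapply(tracks, function(t) as.integer(t$n_elements),
                        integer(1)),
    coverage_bp = vapply(tracks, function(t) t$coverage_bp, numeric(1)),
    mean_segment_length = vapply(tracks, function(t)
      if (length(t$start) == 0) NA_real_ else
        t$coverage_bp / length(t$start), numeric(1)),
    stringsAsFactors = FALSE)
}
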