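#' @title Structure-preserving Monte Carlo null models
#' @description
#' Null models generate randomized tracks or suites while preserving
#' declared structural properties of the observed data. Three categories
#' are provided, mirroring the three families of sampling algorithms for
#' suite-level testing: (1) samplers that treat each track separately
#' (randomize positions, preserving the per-chromosome multisets of segment
#' lengths and gaps); (2) samplers that pool segments across the tracks of
#' one suite and re-deal them; (3) samplers across two suites, either
#' pooling elements across everything or permuting whole tracks between
#' suites. All samplers are deterministic given their seed.
#' @name null-models
NULL

# run expr under a temporary RNG state seeded with `seed`; restore afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a reproducible 31-bit sub-seed from a master seed and a counter
.mix_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 2654435) %%
               2147483629)
}

#' Describe a sampler
#'
#' A record of the null model used for one Monte Carlo test: its category,
#' variant options, the list of structural properties every draw preserves,
#' and the seed. Carried in test results for provenance.
#'
#' @param category `"per-track"`, `"pooled-within-suite"` or
#'   `"across-suites"`.
#' @param variant named list of option values.
#' @param preserve character vector of preserved properties.
#' @param seed integer seed or NULL.
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(category, variant = list(), preserve = character(),
                         seed = NULL) {
  category <- match.arg(category,
                        c("per-track", "pooled-within-suite", "across-suites"))
  structure(list(category = category, variant = variant,
                 preserve = preserve, seed = seed),
            class = "sampler_spec")
}

#' @export
print.sampler_spec <- function(x, ...) {
  cat(sprintf("<sampler_spec %s; preserves: %s; seed: %s>\n", x$category,
              paste(x$preserve, collapse = ", "),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Randomize one track preserving segment structure
#'
#' Per chromosome, the multiset of segment lengths and the multiset of
#' gaps (inter-segment distances, including the two flanks to the
#' chromosome ends) are independently permuted and laid out alternately
#' starting with a gap. Every draw therefore has the same segment count,
#' the same per-chromosome length multiset (hence the same coverage) and
#' the same gap multiset as the input; only the arrangement changes. A
#' permutation that would place a zero-length flank between two segments
#' (merging them) is rejected and redrawn, so the segment count is always
#' preserved. Segments never move across chromosomes.
#'
#' @param x a non-empty track.
#' @param seed integer seed (NULL = use current RNG state).
#' @return a randomized `track` with the same genome and label.
#' @export
sample_track_preserving_structure <- function(x, seed = NULL) {
  stopifnot(inherits(x, "track"))
  if (length(x$start) == 0) stop("cannot randomize an empty track")
  .with_seed(seed, {
    out_c <- character(0); out_s <- numeric(0); out_e <- numeric(0)
    for (ch in unique(x$chrom)) {
      s <- .chrom_segs(x, ch)
      k <- length(s$start)
      len <- x$genome$lengths[[ch]]
      L <- s$end - s$start
      gaps <- c(s$start[1], if (k > 1) s$start[-1] - s$end[-k], len - s$end[k])
      for (attempt in 1:1000) {
        gp <- if (length(gaps) > 1) sample(gaps) else gaps
        if (k == 1 || all(gp[2:k] > 0)) break
        if (attempt == 1000)
          stop("could not place segments without merging on ", ch)
      }
      Lp <- if (k > 1) sample(L) else L
      starts <- cumsum(gp[1:k]) + c(0, cumsum(Lp))[1:k]
      out_c <- c(out_c, rep(ch, k))
      out_s <- c(out_s, starts); out_e <- c(out_e, starts + Lp)
    }
    track(x$genome, out_c, out_s, out_e, label = x$label,
          n_elements = x$n_elements)
  })
}

#' Randomize every track of a suite independently
#'
#' Category-1 sampler: applies [sample_track_preserving_structure()] to
#' each track with an independent sub-seed derived from the master seed, so
#' the same master seed reproduces the whole suite and different tracks are
#' randomized independently.
#'
#' @param tracks list of non-empty tracks.
#' @param seed master integer seed (NULL = current RNG state).
#' @return list of randomized tracks in suite order.
#' @export
sample_suite_per_track <- function(tracks, seed = NULL) {
  stopifnot(length(tracks) >= 1)
  if (is.null(seed))
    return(lapply(tracks, sample_track_preserving_structure))
  lapply(seq_along(tracks), function(i)
    sample_track_preserving_structure(tracks[[i]], .mix_seed(seed, i)))
}

#' Pool segments across a suite and re-deal them
#'
#' Category-2 sampler: all segments (with their genomic positions) are
#' placed in one pool shared across the suite, then each output track
#' receives segments from the pool. With `preserve_counts` each track gets
#' exactly its own segment count back; otherwise counts are
#' multinomial-uniform over tracks (total preserved). Without replacement
#' the pool is partitioned (segment conservation across the suite); with
#' replacement segments are drawn independently. Segments dealt to the same
#' output track that overlap or touch are merged at normalization; the
#' pre-merge count is kept in `n_elements`.
#'
#' @param tracks list of >= 2 tracks on one genome.
#' @param preserve_counts preserve each track's segment count (default TRUE).
#' @param replacement draw with replacement (default FALSE).
#' @param seed integer seed.
#' @return list of tracks in suite order.
#' @export
sample_suite_pooled <- function(tracks, preserve_counts = TRUE,
                                replacement = FALSE, seed = NULL) {
  stopifnot(length(tracks) >= 2)
  for (t in tracks[-1]) .check_same_genome(tracks[[1]], t)
  genome <- tracks[[1]]$genome
  pool <- do.call(rbind, lapply(tracks, function(t)
    data.frame(chrom = t$chrom, start = t$start, end = t$end,
               stringsAsFactors = FALSE)))
  np <- nrow(pool)
  n <- length(tracks)
  .with_seed(seed, {
    counts <- if (preserve_counts)
      vapply(tracks, n_segments, integer(1))
    else as.integer(stats::rmultinom(1, np, rep(1 / n, n)))
    if (!replacement && sum(counts) > np)
      stop("pool too small to supply all per-track counts without replacement")
    idx <- if (replacement)
      lapply(counts, function(k) sample.int(np, k, replace = TRUE))
    else {
      perm <- sample.int(np)
      split(perm, rep(seq_len(n), counts))[as.character(seq_len(n))]
    }
    lapply(seq_len(n), function(i) {
      rows <- idx[[i]]
      if (is.null(rows)) rows <- integer(0)
      track(genome, pool$chrom[rows], pool$start[rows], pool$end[rows],
            label = tracks[[i]]$label, n_elements = length(rows))
    })
  })
}

#' Randomize across two suites
#'
#' Category-3 sampler, two modes. `"permute-tracks"` reassigns the track
#' objects to the two suites uniformly at random, preserving the two suite
#' sizes and the multiset of tracks. `"pool-elements"` pools segments
#' across both tracks and suites (as [sample_suite_pooled()] over the
#' concatenation) and re-splits by the original suite sizes.
#'
#' @param tracks1,tracks2 non-empty lists of tracks on one genome.
#' @param mode `"permute-tracks"` or `"pool-elements"`.
#' @param preserve_counts,replacement passed to [sample_suite_pooled()] in
#'   pool-elements mode.
#' @param seed integer seed.
#' @return list with elements `suite1`, `suite2`.
#' @export
sample_across_suites <- function(tracks1, tracks2,
                                 mode = c("permute-tracks", "pool-elements"),
                                 preserve_counts = TRUE, replacement = FALSE,
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(tracks1) >= 1, length(tracks2) >= 1)
  n1 <- length(tracks1); n2 <- length(tracks2)
  if (mode == "permute-tracks") {
    all_tracks <- c(tracks1, tracks2)
    .with_seed(seed, {
      perm <- sample.int(n1 + n2)
      list(suite1 = all_tracks[perm[seq_len(n1)]],
           suite2 = all_tracks[perm[n1 + seq_len(n2)]])
    })
  } else {
    pooled <- sample_suite_pooled(c(tracks1, tracks2),
                                  preserve_counts = preserve_counts,
                                  replacement = replacement, seed = seed)
    list(suite1 = pooled[seq_len(n1)], suite2 = pooled[n1 + seq_len(n2)])
  }
}
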