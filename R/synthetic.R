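#' @title Synthetic suites with known latent structure
#' @description
#' Generates suites of tracks from the exact latent model the tetrachoric
#' statistic assumes, so parameter recovery is a well-posed check: the
#' genome is divided into blocks of `block_bp` base pairs; each block
#' carries a latent standard-normal master signal `S`; track `i` carries
#' `X_i = rho_i * S + sqrt(1 - rho_i^2) * eps_i` with independent
#' block-level noise, and covers a block when `X_i` exceeds the normal
#' quantile matching its target coverage fraction. Blocks make thresholded
#' tracks peak-like (multi-bp segments) instead of bp-level salt and
#' pepper. The latent correlation of track `i` with the query (the
#' thresholded master signal) is `rho_i`; between tracks `i` and `j` it is
#' `rho_i * rho_j`.
#' @name synthetic-tracks
NULL

#' Specification of a synthetic suite
#'
#' @param genome a `genome_def`.
#' @param n_tracks number of suite tracks.
#' @param coverage_fractions per-track target coverage fractions in (0, 1)
#'   (recycled to `n_tracks`).
#' @param latent_model `"independent"`, `"shared-signal"`,
#'   `"planted-pair"` or `"planted-bin"`.
#' @param rho latent loadings on the master signal, recycled to `n_tracks`
#'   (shared-signal); for planted-pair, the mutual correlation of the
#'   planted pair (tracks 1 and 2); for planted-bin, the shared loading of
#'   all tracks inside the planted bin. Ignored for independent.
#' @param planted_bin for planted-bin: list(chrom, start, end) delimiting
#'   the region where tracks share signal.
#' @param block_bp latent block size in bp (default 50): sets the scale of
#'   generated segment lengths.
#' @param query_fraction coverage fraction of the generated query track
#'   (the thresholded master signal); NULL for no query.
#' @param seed integer seed; the same spec generates identical suites.
#' @return object of class `synthetic_suite_spec`.
#' @export
synthetic_suite_spec <- function(genome, n_tracks,
                                 coverage_fractions = 0.1,
                                 latent_model = c("independent",
                                                  "shared-signal",
                                                  "planted-pair",
                                                  "planted-bin"),
                                 rho = 0, planted_bin = NULL, block_bp = 50,
                                 query_fraction = NULL, seed = 1) {
  latent_model <- match.arg(latent_model)
  stopifnot(inherits(genome, "genome_def"), n_tracks >= 1, block_bp >= 1)
  fr <- rep_len(coverage_fractions, n_tracks)
  if (any(fr <= 0) || any(fr >= 1))
    stop("coverage fractions must lie strictly in (0, 1)")
  if (latent_model == "shared-signal") {
    rho <- rep_len(rho, n_tracks)
  } else if (latent_model %in% c("planted-pair", "planted-bin")) {
    stopifnot(length(rho) == 1, rho >= 0, rho < 1)
    if (latent_model == "planted-pair" && n_tracks < 2)
      stop("planted-pair needs at least 2 tracks")
    if (latent_model == "planted-bin" && is.null(planted_bin))
      stop("planted-bin needs a planted_bin region")
  } else rho <- rep(0, n_tracks)
  if (any(abs(rho) >= 1)) stop("rho values must lie in (-1, 1)")
  structure(list(genome = genome, n_tracks = n_tracks,
                 coverage_fractions = fr, latent_model = latent_model,
                 rho = rho, planted_bin = planted_bin, block_bp = block_bp,
                 query_fraction = query_fraction, seed = seed),
            class = "synthetic_suite_spec")
}

# block boundaries for one chromosome: starts and ends, last block truncated
.blocks <- function(len, block_bp) {
  starts <- seq(0, len - 1, by = block_bp)
  list(start = starts, end = pmin(starts + block_bp, len))
}

# turn a logical vector of covered blocks into a track's intervals
.blocks_to_segments <- function(covered, blk) {
  i <- which(covered)
  list(start = blk$start[i], end = blk$end[i])
}

#' Generate a synthetic suite
#'
#' @param spec a [synthetic_suite_spec()].
#' @return list with `tracks` (list of [track()]), `query` (a `track` or
#'   NULL), and `truth`: the generative record (per-track loadings
#'   `rho`, pairwise latent correlations, coverage targets, planted
#'   locations).
#' @examples
#' g <- genome_definition(c(chr1 = 10000))
#' sp <- synthetic_suite_spec(g, 3, 0.2, "shared-signal",
#'                            rho = c(0.8, 0.5, 0.2),
#'                            query_fraction = 0.2, seed = 42)
#' suite <- generate_suite(sp)
#' length(suite$tracks)
#' @export
generate_suite <- function(spec) {
  stopifnot(inherits(spec, "synthetic_suite_spec"))
  g <- spec$genome
  n <- spec$n_tracks
  loadings <- switch(spec$latent_model,
    independent = rep(0, n),
    `shared-signal` = spec$rho,
    `planted-pair` = c(sqrt(spec$rho), sqrt(spec$rho), rep(0, n - 2)),
    `planted-bin` = rep(spec$rho, n))
  .with_seed(spec$seed, {
    per_chrom <- lapply(g$chroms, function(ch) {
      blk <- .blocks(g$lengths[[ch]], spec$block_bp)
      nb <- length(blk$start)
      S <- stats::rnorm(nb)
      lat <- vapply(seq_len(n), function(i) {
        eps <- stats::rnorm(nb)
        lam <- rep(loadings[i], nb)
        if (spec$latent_model == "planted-bin") {
          pb <- spec$planted_bin
          inside <- pb$chrom == ch & blk$start < pb$end & blk$end > pb$start
          lam[!inside] <- 0
        }
        lam * S + sqrt(1 - lam^2) * eps
      }, numeric(nb))
      list(chrom = ch, blk = blk, S = S, lat = lat)
    })
    tracks <- lapply(seq_len(n), function(i) {
      thr <- stats::qnorm(spec$coverage_fractions[i], lower.tail = FALSE)
      cs <- character(0); ss <- numeric(0); es <- numeric(0)
      for (pc in per_chrom) {
        segs <- .blocks_to_segments(pc$lat[, i] > thr, pc$blk)
        cs <- c(cs, rep(pc$chrom, length(segs$start)))
        ss <- c(ss, segs$start); es <- c(es, segs$end)
      }
      track(g, cs, ss, es, label = sprintf("track%02d", i))
    })
    query <- NULL
    if (!is.null(spec$query_fraction)) {
      thr <- stats::qnorm(spec$query_fraction, lower.tail = FALSE)
      cs <- character(0); ss <- numeric(0); es <- numeric(0)
      for (pc in per_chrom) {
        segs <- .blocks_to_segments(pc$S > thr, pc$blk)
        cs <- c(cs, rep(pc$chrom, length(segs$start)))
        ss <- c(ss, segs$start); es <- c(es, segs$end)
      }
      query <- track(g, cs, ss, es, label = "query")
    }
    truth <- list(model = spec$latent_model, rho_query = loadings,
                  rho_pairwise = outer(loadings, loadings),
                  coverage_fractions = spec$coverage_fractions,
                  planted_bin = spec$planted_bin,
                  planted_pair = if (spec$latent_model == "planted-pair")
                    c(1L, 2L) else NULL,
                  block_bp = spec$block_bp, seed = spec$seed)
    if (spec$latent_model == "planted-bin")
      diag(truth$rho_pairwise) <- 1
    list(tracks = tracks, query = query, truth = truth)
  })
}

#' Materialize a synthetic suite on disk as a GSuite
#'
#' Writes one BED file per track (plus `query.bed` when the spec has a
#' query), a `genome.chrom.sizes` file, and a GSuite file referencing the
#' BED files with the ground truth embedded as metadata columns
#' (`true_rho`, `coverage_fraction`).
#'
#' @param dir writable output directory (created if missing).
#' @param spec a [synthetic_suite_spec()].
#' @return list with `gsuite_path`, `suite` (the parsed [gsuite()]),
#'   `genome_path`, `query_path` (or NULL), and `generated` (the
#'   [generate_suite()] result).
#' @export
generate_toy_gsuite <- function(dir, spec) {
  stopifnot(inherits(spec, "synthetic_suite_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_suite(spec)
  paths <- vapply(gen$tracks, function(t) {
    p <- file.path(dir, paste0(t$label, ".bed"))
    write_bed(t, p)
    p
  }, character(1))
  genome_path <- file.path(dir, "genome.chrom.sizes")
  write_chrom_sizes(spec$genome, genome_path)
  query_path <- NULL
  if (!is.null(gen$query)) {
    query_path <- file.path(dir, "query.bed")
    write_bed(gen$query, query_path)
  }
  meta <- data.frame(
    true_rho = format(gen$truth$rho_query, digits = 10, trim = TRUE),
    coverage_fraction = format(spec$coverage_fractions, digits = 10,
                               trim = TRUE),
    stringsAsFactors = FALSE)
  s <- gsuite(paths, titles = vapply(gen$tracks, function(t) t$label,
                                     character(1)),
              metadata = meta,
              headers = c(location = "local", `file-format` = "bed",
                          `track-type` = "segments",
                          genome = spec$genome$name))
  gsuite_path <- file.path(dir, "suite.gsuite")
  write_gsuite(s, gsuite_path)
  list(gsuite_path = gsuite_path, suite = s, genome_path = genome_path,
       query_path = query_path, generated = gen)
}
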