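#' @title Genomic tracks as merged interval sets
#' @description
#' A track is the set of base pairs on a genome covered by its elements.
#' Internally segments are stored 0-based half-open, sorted by genome
#' chromosome order and start, and normalized: overlapping or book-ended
#' input intervals are merged on construction so that a track is a canonical
#' representation of a bp set. Points are 1 bp segments, so one code path
#' serves point and segment tracks alike. The pre-merge element count is
#' retained (`n_elements`) because element-count-preserving null models need
#' it.
#' @name track-class
NULL

# merge sorted-by-anything intervals on ONE chromosome; returns list(start, end)
# merges overlap and adjacency (canonical non-adjacent form)
.merge_intervals <- function(start, end) {
  k <- length(start)
  if (k <= 1) return(list(start = start, end = end))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  ce <- cummax(e)
  new_grp <- c(TRUE, s[-1] > ce[-k])
  grp_last <- c(which(new_grp)[-1] - 1L, k)
  list(start = s[new_grp], end = ce[grp_last])
}

#' Construct a track
#'
#' @param genome a [genome_definition()] object.
#' @param chrom character vector of chromosome names, one per interval.
#' @param start,end numeric vectors of 0-based half-open coordinates.
#' @param label track label used in result tables.
#' @param n_elements original element count before merging; defaults to the
#'   number of input intervals.
#' @return an object of class `track` with fields `genome`, `chrom`,
#'   `start`, `end`, `label`, `coverage_bp`, `n_elements`.
#' @examples
#' g <- genome_definition(c(chr1 = 100))
#' t <- track(g, c("chr1", "chr1"), c(0, 5), c(10, 20), label = "a")
#' t$coverage_bp  # 20: [0,10) and [5,20) merge to [0,20)
#' @export
track <- function(genome, chrom = character(), start = numeric(),
                  end = numeric(), label = "track", n_elements = NULL) {
  stopifnot(inherits(genome, "genome_def"))
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) == 1 && length(start) > 1)
    chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (is.null(n_elements)) n_elements <- length(start)
  bad <- !chrom %in% genome$chroms
  if (any(bad))
    stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(start >= end))
    stop("empty or inverted interval (start >= end)")
  if (any(start < 0) || any(end > genome$lengths[chrom]))
    stop("interval exceeds chromosome bounds")
  # normalize: genome chromosome order, merged within chromosome
  co <- factor(chrom, levels = genome$chroms)
  out_c <- character(0); out_s <- numeric(0); out_e <- numeric(0)
  for (ch in levels(co)[tabulate(co, nbins = length(genome$chroms)) > 0]) {
    i <- which(chrom == ch)
    m <- .merge_intervals(start[i], end[i])
    out_c <- c(out_c, rep(ch, length(m$start)))
    out_s <- c(out_s, m$start); out_e <- c(out_e, m$end)
  }
  structure(list(genome = genome, chrom = out_c, start = out_s, end = out_e,
                 label = label, coverage_bp = sum(out_e - out_s),
                 n_elements = n_elements),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s': %d segments, %s bp on genome '%s'>\n", x$label,
              length(x$start), format(x$coverage_bp, big.mark = ","),
              x$genome$name))
  invisible(x)
}

#' Number of merged segments in a track
#' @param x a `track`.
#' @return integer segment count.
#' @export
n_segments <- function(x) {
  stopifnot(inherits(x, "track"))
  length(x$start)
}

.read_bed_df <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  df[[2]] <- suppressWarnings(as.numeric(df[[2]]))
  df[[3]] <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(df[[2]]) || anyNA(df[[3]]))
    stop("non-numeric coordinates in BED file: ", path)
  df
}

#' Read a BED file as a track
#'
#' Reads a 3+ column BED file (0-based half-open), validates every interval
#' against the genome definition and returns the normalized (sorted, merged)
#' track. Intervals outside chromosome bounds or with `start >= end` are
#' errors, not silently fixed: out-of-bounds intervals usually indicate a
#' genome-version mismatch. Strand and any further columns are ignored; the
#' statistics operate on covered base pairs only. The element count before
#' merging is kept in `n_elements`.
#'
#' @param path path to a BED file.
#' @param genome a `genome_def` the intervals must resolve against.
#' @param label track label; defaults to the file name without extension.
#' @return a [track()].
#' @export
read_bed <- function(path, genome, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  df <- .read_bed_df(path)
  track(genome, df[[1]], df[[2]], df[[3]], label = label,
        n_elements = nrow(df))
}

#' Write a track as BED3
#'
#' Writes the normalized segments; `read_bed(write_bed(t))` reproduces the
#' track exactly.
#'
#' @param x a `track`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(x$start) > 0)
    writeLines(sprintf("%s\t%s\t%s", x$chrom,
                       format(x$start, scientific = FALSE, trim = TRUE),
                       format(x$end, scientific = FALSE, trim = TRUE)), con)
  invisible(NULL)
}

# per-chromosome index helper: list of (start, end) for one chrom
.chrom_segs <- function(x, ch) {
  i <- x$chrom == ch
  list(start = x$start[i], end = x$end[i])
}

# union length of two merged interval lists on one chromosome
.union_len1 <- function(a, b) {
  m <- .merge_intervals(c(a$start, b$start), c(a$end, b$end))
  sum(m$end - m$start)
}

#' Base pairs covered by both of two tracks
#'
#' Exact size of the intersection of the two covered bp sets, computed as
#' `|A| + |B| - |A union B|` per chromosome on the merged representations.
#'
#' @param a,b tracks on the same genome.
#' @return intersection size in bp.
#' @export
intersect_bp <- function(a, b) {
  stopifnot(inherits(a, "track"), inherits(b, "track"))
  .check_same_genome(a, b)
  chs <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chs) == 0) return(0)
  tot <- 0
  for (ch in chs) {
    sa <- .chrom_segs(a, ch); sb <- .chrom_segs(b, ch)
    tot <- tot + sum(sa$end - sa$start) + sum(sb$end - sb$start) -
      .union_len1(sa, sb)
  }
  tot
}

#' Base-pair contingency table for a pair of tracks
#'
#' Counts base pairs covered by both tracks, by each alone, and by neither,
#' over the whole genome universe `N`. Every pairwise co-occurrence
#' statistic is a pure function of this table.
#'
#' @param a,b tracks on the same genome.
#' @param universe_bp optional universe size overriding the genome's `N`
#'   (used when conditioning on a bin); coverages must not exceed it.
#' @return object of class `contingency_table` with fields `n_both`,
#'   `n_a_only`, `n_b_only`, `n_neither`, `N`.
#' @examples
#' g <- genome_definition(c(chr1 = 100))
#' a <- track(g, "chr1", 0, 30); b <- track(g, "chr1", 20, 50)
#' contingency_table(a, b)  # (10, 20, 20, 50)
#' @export
contingency_table <- function(a, b, universe_bp = NULL) {
  both <- intersect_bp(a, b)
  N <- if (is.null(universe_bp)) a$genome$N else universe_bp
  ct <- new_contingency_table(both, a$coverage_bp - both,
                              b$coverage_bp - both,
                              N - a$coverage_bp - b$coverage_bp + both)
  ct
}

#' Track coverage within one genome region
#'
#' @param x a `track`.
#' @param chrom,start,end a region in 0-based half-open coordinates.
#' @return bp of track coverage intersecting the region.
#' @export
coverage_in_bin <- function(x, chrom, start, end) {
  stopifnot(inherits(x, "track"))
  if (!chrom %in% x$genome$chroms) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > x$genome$lengths[[chrom]] || start >= end)
    stop("bin must satisfy 0 <= start < end <= chromosome length")
  s <- .chrom_segs(x, chrom)
  sum(pmax(0, pmin(s$end, end) - pmax(s$start, start)))
}

#' Clip a track to one region
#'
#' Returns the track restricted to the region (segments truncated at the
#' region edges). Used by binned co-occurrence, where the bin replaces the
#' genome as the bp universe.
#'
#' @inheritParams coverage_in_bin
#' @return a `track` whose segments all lie within the region.
#' @export
clip_track <- function(x, chrom, start, end) {
  stopifnot(inherits(x, "track"))
  s <- .chrom_segs(x, chrom)
  ns <- pmax(s$start, start); ne <- pmin(s$end, end)
  keep <- ns < ne
  track(x$genome, rep(chrom, sum(keep)), ns[keep], ne[keep],
        label = x$label)
}

#' Base pairs covered by at least k tracks
#'
#' The higher-order coverage-depth statistic: how many base pairs are
#' covered by at least `k` of the tracks in a suite ("covered by more than
#' half of the tracks" is `k = floor(n/2) + 1`). Computed by a single sweep
#' over all segment boundaries, not by pairwise decomposition.
#'
#' @param tracks list of tracks on one genome.
#' @param k minimum number of covering tracks, `1 <= k <= length(tracks)`.
#' @return bp count.
#' @examples
#' g <- genome_definition(c(chr1 = 100))
#' ts <- list(track(g, "chr1", 0, 10), track(g, "chr1", 0, 10),
#'            track(g, "chr1", 50, 60))
#' coverage_depth_count(ts, 2)  # 10
#' @export
coverage_depth_count <- function(tracks, k) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  for (t in tracks) stopifnot(inherits(t, "track"))
  for (t in tracks[-1]) .check_same_genome(tracks[[1]], t)
  n <- length(tracks)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != floor(k))
    stop("k must be an integer in 1..", n)
  chs <- unique(unlist(lapply(tracks, function(t) unique(t$chrom))))
  tot <- 0
  for (ch in chs) {
    pos <- numeric(0); delta <- numeric(0)
    for (t in tracks) {
      s <- .chrom_segs(t, ch)
      pos <- c(pos, s$start, s$end)
      delta <- c(delta, rep(1, length(s$start)), rep(-1, length(s$end)))
    }
    o <- order(pos, -delta)  # starts before ends at equal position
    pos <- pos[o]; depth <- cumsum(delta[o])
    if (length(pos) > 1) {
      w <- diff(pos)
      tot <- tot + sum(w[depth[-length(depth)] >= k])
    }
  }
  tot
}
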