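#' Genome definition
#'
#' A genome definition anchors all tracks: an ordered set of named
#' chromosomes with lengths. Its total size `N` (sum of chromosome lengths)
#' is the base-pair universe used by every contingency table, so two tracks
#' can only be compared when they share a genome definition.
#'
#' @param chromosomes a named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a two-column data.frame
#'   (name, length).
#' @param name text label for the genome build.
#' @return an object of class `genome_def` with fields `name`, `chroms`
#'   (character), `lengths` (named numeric) and `N`.
#' @examples
#' g <- genome_definition(c(chr1 = 1000, chr2 = 500), name = "toy")
#' g$N
#' @export
genome_definition <- function(chromosomes, name = "genome") {
  if (is.data.frame(chromosomes)) {
    stopifnot(ncol(chromosomes) >= 2)
    lens <- as.numeric(chromosomes[[2]])
    names(lens) <- as.character(chromosomes[[1]])
    chromosomes <- lens
  }
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a named vector of lengths")
  lens <- as.numeric(chromosomes)
  if (any(!is.finite(lens)) || any(lens <= 0) || any(lens != floor(lens)))
    stop("chromosome lengths must be strictly positive integers")
  if (anyDuplicated(names(chromosomes)))
    stop("chromosome names must be unique")
  structure(
    list(name = name, chroms = names(chromosomes), lengths = lens |>
           stats::setNames(names(chromosomes)), N = sum(lens)),
    class = "genome_def")
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def '%s': %d chromosomes, N = %s bp>\n",
              x$name, length(x$chroms), format(x$N, big.mark = ",")))
  invisible(x)
}

#' Read a chrom.sizes genome definition
#'
#' Reads the standard two-column tab-separated `chrom.sizes` layout
#' (chromosome name, length in bp).
#'
#' @param path path to a chrom.sizes file.
#' @param name genome label; defaults to the file name without extension.
#' @return a [genome_definition()] object.
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  genome_definition(stats::setNames(as.numeric(df$length),
                                    as.character(df$chrom)), name = name)
}

#' Write a chrom.sizes file
#'
#' @param genome a `genome_def`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_def"))
  utils::write.table(
    data.frame(genome$chroms, format(genome$lengths, scientific = FALSE,
                                     trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

.check_same_genome <- function(a, b) {
  ga <- a$genome; gb <- b$genome
  if (!identical(ga$chroms, gb$chroms) ||
      !identical(unname(ga$lengths), unname(gb$lengths)))
    stop("tracks are anchored to different genome definitions")
  invisible(TRUE)
}

#' Fixed-width genome bins
#'
#' Tiles every chromosome left-to-right with windows of the given width; the
#' last bin of a chromosome is truncated at the chromosome end. The union of
#' bins covers the genome exactly once (total bin bp equals `N`).
#'
#' @param genome a `genome_def`.
#' @param width bin width in bp (>= 1).
#' @return a `bin_spec`: a data.frame-backed object with columns
#'   `name`, `chrom`, `start`, `end` (0-based half-open) and attribute
#'   `source = "fixed-width"`.
#' @examples
#' g <- genome_definition(c(chr1 = 100))
#' make_bins(g, 40)
#' @export
make_bins <- function(genome, width) {
  stopifnot(inherits(genome, "genome_def"))
  if (!is.numeric(width) || length(width) != 1 || width < 1 ||
      width != floor(width))
    stop("width must be a positive integer")
  pieces <- lapply(genome$chroms, function(ch) {
    len <- genome$lengths[[ch]]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, len),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  df <- data.frame(name = sprintf("%s:%s-%s", df$chrom,
                                  format(df$start, scientific = FALSE, trim = TRUE),
                                  format(df$end, scientific = FALSE, trim = TRUE)),
                   df, stringsAsFactors = FALSE)
  bin_spec(df, genome, source = "fixed-width")
}

#' Construct a bin specification
#'
#' Bins are named genome regions used as units of aggregation in binned
#' occurrence/co-occurrence analyses. Unlike tracks, bins are not merged:
#' each row is kept as supplied (bins may touch but must be named uniquely).
#'
#' @param bins data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open); `name` may be omitted and is then synthesized
#'   from the coordinates.
#' @param genome a `genome_def` the bins must lie within.
#' @param source provenance tag, `"fixed-width"` or `"user-supplied"`.
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(bins, genome, source = "user-supplied") {
  stopifnot(inherits(genome, "genome_def"), is.data.frame(bins))
  if (!all(c("chrom", "start", "end") %in% names(bins)))
    stop("bins need columns chrom, start, end")
  if (!"name" %in% names(bins))
    bins$name <- sprintf("%s:%s-%s", bins$chrom,
                         format(bins$start, scientific = FALSE, trim = TRUE),
                         format(bins$end, scientific = FALSE, trim = TRUE))
  bins <- bins[, c("name", "chrom", "start", "end")]
  if (nrow(bins) == 0) stop("empty bin specification")
  if (anyDuplicated(bins$name)) stop("bin names must be unique")
  bad <- !bins$chrom %in% genome$chroms
  if (any(bad))
    stop("unknown chromosome in bins: ", paste(unique(bins$chrom[bad]),
                                               collapse = ", "))
  if (any(bins$start < 0) || any(bins$end > genome$lengths[bins$chrom]) ||
      any(bins$start >= bins$end))
    stop("bins must satisfy 0 <= start < end <= chromosome length")
  structure(list(bins = bins, genome = genome, source = source),
            class = "bin_spec")
}

#' Read bins from a BED file
#'
#' Reads BED intervals as bins without merging them; the name column
#' (column 4) is used for bin names when present.
#'
#' @inheritParams read_bed
#' @return a `bin_spec`.
#' @export
read_bed_bins <- function(path, genome) {
  df <- .read_bed_df(path)
  if (ncol(df) >= 4) {
    bins <- data.frame(name = as.character(df[[4]]), chrom = df[[1]],
                       start = df[[2]], end = df[[3]],
                       stringsAsFactors = FALSE)
  } else {
    bins <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                       stringsAsFactors = FALSE)
  }
  bin_spec(bins, genome, source = "user-supplied")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("<bin_spec: %d bins (%s) on genome '%s'>\n",
              nrow(x$bins), x$source, x$genome$name))
  invisible(x)
}
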