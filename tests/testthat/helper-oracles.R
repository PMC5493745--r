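# Independent brute-force oracles: every interval-set result is checked
# against explicit per-basepair boolean/depth arrays. These helpers never
# call the package's own set operations.

# logical coverage vector of a track on one chromosome (bp i = index i+1)
bp_vector <- function(tr, ch) {
  v <- logical(tr$genome$lengths[[ch]])
  i <- which(tr$chrom == ch)
  for (k in i) v[(tr$start[k] + 1):tr$end[k]] <- TRUE
  v
}

# whole-genome coverage vector (concatenated in genome chromosome order)
bp_genome_vector <- function(tr) {
  unlist(lapply(tr$genome$chroms, function(ch) bp_vector(tr, ch)))
}

oracle_intersect_bp <- function(a, b) {
  sum(bp_genome_vector(a) & bp_genome_vector(b))
}

oracle_contingency <- function(a, b) {
  va <- bp_genome_vector(a); vb <- bp_genome_vector(b)
  c(n_both = sum(va & vb), n_a_only = sum(va & !vb),
    n_b_only = sum(!va & vb), n_neither = sum(!va & !vb))
}

oracle_coverage_in_bin <- function(tr, ch, s, e) {
  sum(bp_vector(tr, ch)[(s + 1):e])
}

# depth vector over the whole genome
oracle_depth <- function(tracks) {
  Reduce(`+`, lapply(tracks, function(t) as.integer(bp_genome_vector(t))))
}

# random (possibly overlapping) raw intervals -> normalized track
random_track <- function(genome, n_segs = 8, max_len = NULL, label = "t") {
  chs <- sample(genome$chroms, n_segs, replace = TRUE)
  if (is.null(max_len)) max_len <- max(3, min(genome$lengths) %/% 4)
  starts <- ends <- numeric(n_segs)
  for (i in seq_len(n_segs)) {
    len <- sample.int(max_len, 1)
    cl <- genome$lengths[[chs[i]]]
    len <- min(len, cl)
    starts[i] <- sample.int(cl - len + 1, 1) - 1
    ends[i] <- starts[i] + len
  }
  track(genome, chs, starts, ends, label = label)
}

toy_genome <- function(n = 200, chroms = 1) {
  genome_definition(stats::setNames(rep(n, chroms),
                                    paste0("chr", seq_len(chroms))))
}

# direct formula statistics on an oracle table (independent route)
oracle_jaccard <- function(o) unname(o["n_both"] /
                                       (o["n_both"] + o["n_a_only"] + o["n_b_only"]))
oracle_forbes <- function(o) {
  N <- sum(o)
  unname(N * o["n_both"] /
           ((o["n_both"] + o["n_a_only"]) * (o["n_both"] + o["n_b_only"])))
}
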