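#' @title Pairwise co-occurrence statistics (T)
#' @description
#' Every pairwise track statistic here is a pure function of the base-pair
#' contingency table of two tracks: each base pair of the genome is one
#' observation, classified as covered by both tracks, one, or neither.
#' Three statistics are provided. The Jaccard index is intersection over
#' union; it is strongly confounded by track size and is not recommended for
#' ranking. The Forbes coefficient is the ratio of observed to expected
#' co-coverage under independence (`N*|A^B| / (|A|*|B|)`), equal to 1 at
#' independence. The tetrachoric correlation is the correlation `rho` of a
#' latent bivariate standard normal assumed to generate the two binary
#' coverage indicators by thresholding; it is estimated by maximum
#' likelihood with thresholds fixed at the normal quantiles of the marginal
#' coverage fractions.
#' @name pairwise-stats
NULL

#' Construct a base-pair contingency table
#'
#' @param n_both,n_a_only,n_b_only,n_neither non-negative bp counts; their
#'   sum is the universe size `N`.
#' @return object of class `contingency_table`.
#' @export
new_contingency_table <- function(n_both, n_a_only, n_b_only, n_neither) {
  cells <- c(n_both, n_a_only, n_b_only, n_neither)
  if (length(cells) != 4 || any(!is.finite(cells)) || any(cells < 0))
    stop("contingency table cells must be four non-negative finite counts")
  structure(list(n_both = n_both, n_a_only = n_a_only, n_b_only = n_b_only,
                 n_neither = n_neither, N = sum(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(paste0("<contingency_table N=%s: both=%s, a-only=%s, ",
                     "b-only=%s, neither=%s>\n"),
              format(x$N, big.mark = ","), x$n_both, x$n_a_only, x$n_b_only,
              x$n_neither))
  invisible(x)
}

#' Jaccard index of a contingency table
#'
#' `|A^B| / |AuB|`, in `[0, 1]`. Defined as 0 (with a warning) when both
#' tracks are empty. Size-confounded: with equal underlying association,
#' larger tracks get larger Jaccard values, so avoid it for ranking.
#'
#' @param ct a `contingency_table`.
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  u <- ct$n_both + ct$n_a_only + ct$n_b_only
  if (u == 0) {
    warning("Jaccard of two empty tracks defined as 0")
    return(0)
  }
  ct$n_both / u
}

#' Forbes coefficient of a contingency table
#'
#' `N * |A^B| / (|A| * |B|)`: the ratio of observed co-coverage to the
#' co-coverage expected if the two tracks covered base pairs independently.
#' Equals 1 at independence, `N/|A|` when the tracks are identical, 0 when
#' disjoint. Undefined (an error) when either track is empty.
#'
#' @param ct a `contingency_table`.
#' @return non-negative numeric.
#' @export
forbes <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  na <- ct$n_both + ct$n_a_only
  nb <- ct$n_both + ct$n_b_only
  if (na == 0 || nb == 0)
    stop("Forbes undefined for empty track")
  ct$N * ct$n_both / (na * nb)
}

# upper-tail orthant probability P(X > h, Y > k) for standard bivariate
# normal with correlation rho, by 1-D quadrature:
#   integral over x > h of dnorm(x) * P(Y > k | X = x) dx
.bvn_upper <- function(h, k, rho) {
  if (abs(rho) < 1e-12)
    return(stats::pnorm(h, lower.tail = FALSE) *
             stats::pnorm(k, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((k - rho * x) / s, lower.tail = FALSE)
  stats::integrate(f, lower = h, upper = Inf, rel.tol = 1e-10,
                   abs.tol = 1e-12)$value
}

#' Tetrachoric correlation of a contingency table
#'
#' Assumes each base pair carries a latent bivariate standard-normal pair
#' `(X, Y)` with correlation `rho`; track A covers the base pair when
#' `X` exceeds a threshold chosen so that `P(covered)` matches A's marginal
#' coverage fraction, and likewise for B. With thresholds fixed at the
#' normal quantiles of the empirical margins, `rho` is estimated by bounded
#' 1-D maximization of the multinomial likelihood of the four cells over
#' `(-1+1e-6, 1-1e-6)`. When any cell is zero a 0.5 continuity correction is
#' added to the zero cells before estimation (toggle with `continuity`).
#'
#' A degenerate margin (an empty track, or one covering the whole genome)
#' leaves `rho` unidentified and is an error.
#'
#' On a median-split table (both margins `N/2`) the estimate matches the
#' closed form `rho = sin(2*pi*(n_both/N - 1/4))`.
#'
#' @param ct a `contingency_table`.
#' @param continuity apply the 0.5 correction to zero cells (default TRUE).
#' @return object of class `tetrachoric_result` with fields `rho`
#'   (in `[-1, 1]`), `converged`, and `method = "maximum-likelihood"`.
#' @export
tetrachoric <- function(ct, continuity = TRUE) {
  stopifnot(inherits(ct, "contingency_table"))
  cells <- c(ct$n_both, ct$n_a_only, ct$n_b_only, ct$n_neither)
  na <- cells[1] + cells[2]; nb <- cells[1] + cells[3]
  if (na == 0 || nb == 0 || na == ct$N || nb == ct$N)
    stop("tetrachoric undefined for degenerate margin")
  if (continuity && any(cells == 0))
    cells[cells == 0] <- 0.5
  N <- sum(cells)
  pa <- (cells[1] + cells[2]) / N
  pb <- (cells[1] + cells[3]) / N
  h <- stats::qnorm(pa, lower.tail = FALSE)
  k <- stats::qnorm(pb, lower.tail = FALSE)
  eps <- 1e-6
  negll <- function(rho) {
    p11 <- .bvn_upper(h, k, rho)
    p10 <- pa - p11; p01 <- pb - p11
    p00 <- 1 - pa - pb + p11
    p <- pmax(c(p11, p10, p01, p00), 1e-300)
    -sum(cells * log(p))
  }
  opt <- stats::optimize(negll, interval = c(-1 + eps, 1 - eps),
                         tol = 1e-9)
  rho <- opt$minimum
  converged <- is.finite(opt$objective) && abs(rho) < 1 - 1e-5
  # optimize() cannot land exactly on a boundary; snap near-boundary fits
  structure(list(rho = rho, converged = converged,
                 method = "maximum-likelihood"),
            class = "tetrachoric_result")
}

#' @export
print.tetrachoric_result <- function(x, ...) {
  cat(sprintf("<tetrachoric rho = %.4f (%s%s)>\n", x$rho, x$method,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

.stat_names <- c("jaccard", "forbes", "tetrachoric")

# resolve a statistic name to a function contingency_table -> numeric
.stat_fun <- function(stat) {
  stat <- match.arg(stat, .stat_names)
  switch(stat,
         jaccard = jaccard,
         forbes = forbes,
         tetrachoric = function(ct) tetrachoric(ct)$rho)
}

#' Pairwise track statistic T
#'
#' Computes the chosen co-occurrence statistic for a pair of tracks by
#' composing [contingency_table()] with the statistic. Larger values always
#' mean more co-occurrence.
#'
#' @param a,b tracks on the same genome.
#' @param stat one of `"jaccard"`, `"forbes"`, `"tetrachoric"`.
#' @return numeric statistic value.
#' @export
pairwise_T <- function(a, b, stat = "forbes") {
  f <- .stat_fun(stat)
  f(contingency_table(a, b))
}
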