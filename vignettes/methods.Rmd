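---
title: "Statistical methods for track-collection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for track-collection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracksuite)
```

## Scope and model of the data

`tracksuite` analyses *suites* of genomic tracks. A track is modelled
purely as the set of base pairs it covers on a fixed genome definition
(ordered chromosomes with lengths, total size $N$). Coordinates are
0-based half-open throughout (the BED convention); points are 1 bp
segments so a single code path serves point and segment tracks. On
construction every track is *normalized*: intervals are sorted, and
overlapping or book-ended intervals are merged, so a track is a canonical
representation of its bp set. The element count before merging is kept,
because count-preserving null models need it. Strand is ignored — all
statistics are defined on covered base pairs. Intervals outside
chromosome bounds are errors rather than being clipped, since they
usually indicate a genome-version mismatch.

The bp universe $N$ is the full chromosome length sum. Assembly gaps are
not excluded; a user who wants a gap-masked universe can supply a genome
definition whose chromosome lengths describe the unmasked portion, or
restrict analyses to bins.

## The statistic hierarchy

Every pairwise comparison reduces to the $2\times2$ base-pair
contingency table $(n_{11}, n_{10}, n_{01}, n_{00})$ with
$\sum = N$: each base pair is one observation, cross-classified by
coverage in the two tracks. Three pairwise statistics $T$ are provided:

* Jaccard $n_{11}/(n_{11}+n_{10}+n_{01})$, defined as 0 for two empty
  tracks (with a warning). Jaccard is strongly size-confounded: at equal
  underlying association, bigger tracks score higher. The package keeps
  it for compatibility but the documentation recommends against it
  wherever tracks are *ranked*; the acceptance suite demonstrates the
  confounding on simulated data.
* Forbes $N n_{11} / ((n_{11}+n_{10})(n_{11}+n_{01}))$ — observed over
  expected co-coverage under independence; 1 at independence, $N/|A|$
  for identical tracks. Undefined (an error) for an empty track.
* Tetrachoric correlation $\rho$, described below.

Above $T$: the per-track statistic $Q_i$ aggregates
$\{T(A_i, A_j)\}_{j \ne i}$ (mean by default, max/min selectable — the
mean form is $\frac{1}{n-1}\sum_{j\ne i} T(A_i,A_j)$); the suite
statistic $R$ aggregates the $Q_i$ (mean/mean form
$\frac{1}{n}\sum_i Q_i$); the cross-suite statistic is the full
$n_1 \times n_2$ matrix of $T$ values with marginal means. Binned
variants recompute $T$ with a genome bin as the universe ($N \to$ bin
length): the bin-level descriptive statistic deliberately does *not*
correct for genome-wide co-occurrence propensity — that conditioning is
the null model's job (the per-track sampler randomizes genome-wide, so
per-bin p-values are conditional on genome-wide structure). The
higher-order coverage-depth count (bp covered by $\ge k$ tracks) is
computed by one sweep over all segment boundaries; it cannot be obtained
from pairwise tables.

Ranks in all result tables are descending (rank 1 = largest), with
average ranks for ties and a stable secondary ordering by label, so
output tables are reproducible.

## Tetrachoric correlation: estimation and numerics

The tetrachoric model assumes each base pair carries a latent bivariate
standard normal $(X, Y)$ with correlation $\rho$; track A covers the
base pair iff $X > h$, track B iff $Y > k$. The thresholds are fixed at
the normal quantiles of the empirical marginal coverage fractions, which
makes the profile likelihood in $\rho$ one-dimensional. Estimation
maximizes the multinomial log-likelihood of the four cells over
$\rho \in (-1+10^{-6},\, 1-10^{-6})$ with `stats::optimize`. With
thresholds fixed at the empirical margins the maximizer coincides with
the moment condition $P_\rho(X>h, Y>k) = n_{11}/N$, which the tests
exploit as an independent check. The orthant probability is computed by
adaptive 1-D quadrature of
$\int_h^\infty \varphi(x)\,\Phi\!\big((\rho x - k)/\sqrt{1-\rho^2}\big)\,dx$
(no bivariate-normal CDF is required from outside the package).

Numerical choices:

* a zero cell gets a 0.5 continuity correction before estimation
  (toggleable via `continuity`); margins and thresholds are recomputed
  from the corrected cells;
* a degenerate margin (empty track, or track covering the whole genome)
  leaves $\rho$ unidentified and is an error, as are empty tracks under
  Forbes;
* `converged` is reported false when the optimizer lands within
  $10^{-5}$ of the boundary (the estimate is then effectively $\pm 1$);
* on a median-split table (both margins $N/2$) the estimate agrees with
  the closed form $\rho = \sin(2\pi(n_{11}/N - 1/4))$ to $|\Delta\rho| <
  10^{-3}$, which the acceptance suite asserts on a grid of tables.

A base pair is *not* an independent observation in real data (coverage
is autocorrelated along the genome), so tetrachoric standard errors are
not reported; inference is delegated entirely to the Monte Carlo
machinery, which preserves segment structure and therefore the
autocorrelation.

## Null models

Three sampler categories are provided; each declares the properties that
every draw preserves, and the test suite asserts them on thousands of
draws.

**Per-track sampler.** Per chromosome, the multiset of segment lengths
and the multiset of gaps (inter-segment distances including the two
flanks) are independently permuted and laid out alternately starting
with a gap. Each draw preserves the segment count, the per-chromosome
length multiset (hence coverage), and the gap multiset; segments never
change chromosome. This is one concrete reading of "preserve the
empirical distribution of lengths and distances": the randomization is
uniform over the layouts reachable by permutation, *not* uniform over
all feasible placements — a single segment can only start at one of the
observed flank lengths. The placement-uniformity tests accordingly
enumerate permutation layouts as the reference distribution. A
permutation that would put a zero-length flank between two segments
(which would merge them and change the count) is rejected and redrawn;
this only arises when the input track touches a chromosome end.

**Pooled within-suite sampler.** All segments are pooled with their
genomic positions and re-dealt to the output tracks — per-track counts
preserved by default, otherwise multinomial-uniform; without replacement
the pool is partitioned (full conservation), with replacement segments
are drawn independently. Segments dealt to one output track that overlap
are merged at normalization and the pre-merge count recorded. Merging is
deterministic and cheap; a rejection scheme that forbids intra-track
overlap was considered and not adopted as the default because it can
loop on dense suites, and neither policy is bias-free in general.

**Across-suite samplers.** Either whole tracks are permuted between the
two suites (suite sizes preserved; valid when tracks are exchangeable
under the null), or segments are pooled across both suites and re-split.

All randomness flows from a single integer seed per call; per-track and
per-sample sub-seeds are derived by multiplicative counter mixing so
draws are independent yet reproducible, and samplers restore the
caller's RNG state.

## Monte Carlo tests

P-values use the add-one estimator $p = (k+1)/(m+1)$, where $k$ of the
$m$ null statistics are at least as extreme as the observed value
("at least as extreme" is $\ge$, $\le$, or $|x - \bar{x}_{null}| \ge
|obs - \bar{x}_{null}|$ for greater / less / two-sided). The estimator
is strictly positive with minimum $1/(m+1)$ — the honest resolution of a
finite simulation; exact-zero p-values cannot occur. Default
$m = 99$ for exploration; $m = 999$ is recommended for confirmation.
A statistic failure on a null sample is redrawn once and then fatal,
so a silently biased null distribution is impossible.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is reported
alongside raw p-values across the tracks, bins or cells of one
invocation; the choice of adjustment is left visible to the user because
different analyses call for different error rates.

Each result records a multiplicity class derived mechanically from the
statistic and sampler scopes: if either the statistic spans suite tracks
or the sampler draws across tracks, p-values are *integrative*;
otherwise *contrasting* (per-track values comparable across tracks);
depth-based statistics are *higher-order*; independent per-track
descriptors are *trivial*.

Question-level tests compose these pieces:

* **q1** — suite coherence: statistic $R$, per-track sampler, greater
  alternative. The per-track companion ("is the most representative
  track more similar to the rest than any track would be by chance?")
  is implemented as statistic $\max_i Q_i$ with the same sampler; this
  footnoted question is not fully specified in the source material, and
  the max-Q reading is this package's documented interpretation.
* **q2** — per-track query tests, uncentered ($T(q, A_i)$, contrasting)
  and centered ($T(q, A_i) - \frac1n\sum_j T(q, A_j)$, integrative; the
  centered values sum to zero in every sample), plus a suite-level mean
  statistic. The null randomizes the query only, keeping the suite
  fixed.
* **q3** — per-cell statistic is the double-centered matrix entry
  (conditioning on each track's marginal propensity); suite-pair
  statistic is $\max |$normalized cell$|$; null permutes whole tracks
  between suites. Note a structural property: the permutation null of
  tiny suites is coarse — $2+2$ suites admit only 3 distinct partitions
  and hence a minimum attainable p of about $1/3$. Calibration
  experiments use $5+5$ suites (126 partitions). This is a property of
  the null model, not of the implementation.
* **q4/q5** — per-bin statistic is the bin's aggregated value
  (occurrence fraction, or mean pairwise co-occurrence with the bin as
  universe); the suite-level statistic is the variance of the per-bin
  values across bins; null is genome-wide per-track randomization.

## The synthetic generator, and what a green test establishes

The generator divides the genome into blocks of `block_bp` (default
50 bp, chosen so thresholded tracks have realistic multi-bp, peak-like
segments rather than bp-level noise). Each block carries a latent
standard normal master signal $S$; track $i$'s latent value is
$\rho_i S + \sqrt{1-\rho_i^2}\,\varepsilon_i$ with iid block noise, and
the track covers the block when its latent value exceeds the quantile
matching the target coverage fraction. The optional query track
thresholds $S$ itself, so the query–track latent correlation is exactly
$\rho_i$ and the track–track correlation is $\rho_i \rho_j$. Planted
variants concentrate shared signal on a designated pair or a designated
genome region. Ground truth is returned with the suite and, for
materialized suites, embedded as GSuite metadata columns.

This is exactly the latent model the tetrachoric statistic assumes, so
parameter recovery is a well-posed acceptance test. Realized coverage is
binomial over $N/\texttt{block\_bp}$ independent blocks: at $N = 10^5$
and fraction 0.25 the 1-sigma noise is about 1%, and the coverage
acceptance check uses this block-level binomial tolerance (4 sigma)
rather than a fixed band narrower than the generator's own sampling
noise.

What the generator does *not* emulate: read-level noise, mappability and
GC bias, non-stationary segment-length distributions, inter-chromosome
heterogeneity, and long-range dependence beyond the block scale. A green
recovery or calibration test therefore establishes correctness of the
statistics and samplers under the stated latent model — not robustness
to every artefact of real ChIP-seq data.

## Calibration methodology

For every shipped (question, sampler) pairing, observed data are drawn
from the sampler's own null (which guarantees exchangeability with the
null draws), the test is run at $m = 99$, and the rejection count at
$\alpha = 0.05$ over 200 replicates must fall inside the exact binomial
95% acceptance interval. Power checks plant known structure
(a zero-correlation outlier, an associated track or cell, a co-occurring
bin) and require recovery at the extreme rank or minimum p in 80–90% of
seeded replicates, thresholds as stated per question in the test file.

## GSuite dialect

The tabular collection format implemented here: `##key: value` header
lines (keys case-insensitive, unique, unknown keys preserved; recognized
keys `location`, `file-format`, `track-type`, `genome`); one optional
`#uri<TAB>title<TAB>...` column-declaration line whose first two columns
must be `uri` and `title`; tab-separated data rows with `.` as the
missing-value token; and the degenerate form — a plain list of URLs, one
per line, with no `#` lines — is valid. A literal tab inside a field
cannot be escaped and is an error on write. Parse/write round trips are
identity, including header order. Remote URIs are representable and
validatable but never fetched: repository access is out of scope, and
`load_suite_tracks` directs the user to fetch files first.

## Known limitations

* Only location data (points/segments) are supported: no valued
  elements, no signal (function) tracks.
* The bp-level contingency table treats each base pair as one
  observation; all dependence correction is via the structure-preserving
  nulls, so parametric standard errors are deliberately absent.
* The pooled sampler's handling of intra-track overlap (merge at
  normalization) is one of several defensible policies; none is
  bias-free in general.
* Jaccard is retained but size-confounded; Forbes is unbounded above
  and sensitive for very small tracks; tetrachoric is the recommended
  ranking statistic for size-heterogeneous suites.
* The cross-suite permutation test has coarse p-value resolution for
  small suites (see above).
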