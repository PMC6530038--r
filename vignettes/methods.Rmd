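---
title: "Methods: scanning, selecting and aggregating dynamic gene correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, selecting and aggregating dynamic gene correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lahyper)
```

## The model

A gene pair whose correlation depends on an unobserved cellular state shows
*dynamic correlation*. When a third gene's expression tracks that state,
the triple carries a ternary signal that pairwise methods cannot see. For
rows normalised to standard normal scores, the Liquid Association of a
triplet is the expectation of the triple product, `E(XYZ)`, estimated by
its sample mean. Two assumptions make this a valid measure of how the
(X, Y) correlation moves with Z: each row is marginally (near) standard
normal — guaranteed by the normal score transform — and the three pairwise
correlations are near zero, which the package enforces with the screening
interval `(mu - c*sigma, mu + c*sigma)` on the empirical distribution of
all pairwise correlations. Under the screen, the statistic is symmetric in
its three arguments, so the scan can organise work by "scouting gene"
without affecting which triplets score highly.

The pipeline is: normal score transform → correlation screen → per-scout
scan of all eligible pairs → permutation null and local-fdr selection →
gene grouping → lifting to module labels → weighted 3-uniform hypergraph
with fold-change edge weights.

## Tunable parameters

* `c` (screen width, unitless multiples of the pairwise-correlation sd;
  pipeline default 0.5). Small `c` enforces the validity condition
  strictly but leaves few eligible pairs; large `c` admits confounded
  triplets. `correlation_sampling_sd(m) = 1/sqrt(m)` and
  `suggest_screen_constant()` let users match the screen to the null 95%
  CI of a sample correlation (half-width `1.96/sqrt(m)`), the natural
  anchor: with hundreds of samples this is around `c = 0.5`; with fewer
  than a hundred, around `c = 1`.
* `fdr_target` (local fdr at the selection boundary; pipeline default
  0.01, 0.1 for exploratory use). Applied per scouting gene, both tails,
  since dynamic correlation is signed.
* `n_permutations` (default 1): each permutation of a scout row yields one
  null score per eligible pair, so even one shuffle gives thousands of
  null draws; raise it only for very small pair sets.
* `min_fold_change` (default 2 supervised, 10 unsupervised): hyperedge
  retention threshold. `suggest_threshold()` finds the smallest threshold
  whose thresholded graph has a median vertex degree at or below a
  target; a median degree near 4 with hundreds of modules, or near 20
  with tens of modules, keeps the graph visually inspectable.
* `min_cluster_size` (default 100; scaled down with a warning when few
  genes cluster) and the supervised set-size window `[5, 500]`, the usual
  range for informative functional categories.
* `max_zero_fraction` (default 0.10): genes with more zeros than this are
  dropped at load time.

## Numerical and design choices

**Normal scores.** `qnorm(r/(m+1))` with average ranks for ties (van der
Waerden scores): symmetric, bounded, deterministic; tie-free rows have
mean exactly zero. The transform is idempotent up to rank.

**Screen.** `mu` and `sigma` are computed over the `n(n-1)/2` distinct
off-diagonal correlations (no diagonal, no double counting); interval
endpoints are open, so `c = 0` admits nothing. A triplet requires all
three of its pairs to be eligible.

**Local fdr curve.** The observed score density is a Gaussian-kernel
estimate with Silverman's bandwidth on a 512-point grid spanning the
observed scan range plus three bandwidths (a threshold beyond the observed
data cannot select anything, so the grid does not chase the null range).
The fdr is the null/observed density ratio, floored at `1e-10` in the
denominator and capped at 1.

Three choices here were genuinely open and were settled by measurement on
synthetic data with known truth:

1. *Null density.* The null scores of insignificant triplets are
   approximately normal, but a finite permutation sample from
   heterogeneous pairs is a normal *scale mixture*: pairs whose two genes
   share a conditionally-correlated partner have product variance inflated
   by a factor of up to `1 + 2*delta^2`. A kernel estimate of a single
   permutation has sampling holes in its extreme tail (the density ratio
   then dips spuriously and selects isolated null extremes); a plain
   normal fit has tails that are too thin for the mixture. The default is
   therefore an *envelope*: the pointwise maximum of the kernel estimate
   and a normal fit to the same sample. Both pure variants remain
   available (`null_density = "kde"` or `"normal"`).
2. *Pooling the null.* The null density does not change shape from scout
   to scout, so `la_select()` pools the permutation draws of all scouts
   into one null sample used by every scout's curve (`pool_null = TRUE`).
   With one permutation per scout this is the difference between a tail
   estimated from a few thousand draws and one estimated from hundreds of
   thousands: on planted data (below) the per-scout null yields empirical
   FDR between 0.3 and 0.7 at a local-fdr target of 0.1, while the pooled
   envelope null yields 0.0–0.1 at the same recall.
3. *Tail regularization.* The raw density ratio oscillates in sparse
   tails. Each tail is replaced by its minimal non-increasing majorant
   moving outward from the null mode (every value becomes the maximum of
   all values further out, so no value ever decreases). A threshold —
   the innermost grid point at which the regularized curve reaches the
   target — therefore exists only where the *entire* outward tail stays
   at or below target, which is what makes isolated-extreme selection
   rare. A least-squares isotonic fit was considered and rejected: it can
   pull tail values below the raw ratio and is measurably
   anti-conservative here.

**Selection.** Per scout, scores at or beyond a threshold are selected;
the union over scouts is canonicalized to `i < j < k` and deduplicated
(scores are identical across a triplet's three scouts by symmetry).
Eligibility is computed once on the unpermuted data and reused for the
null scan, so observed and null runs cover the same pair universe.
Per-scout permutation seeds derive deterministically from the master seed
with the scout index mixed in; runs are bit-reproducible.

**Grouping.** The pair count matrix `A` adds one to all six ordered cells
of each selected triplet's three pairs, so `sum(A) = 6 * n_triplets`; the
diagonal stays zero. Row correlation uses raw counts (no transform);
all-zero rows (genes in no triplet) are excluded and reported. Clustering
is average-linkage on `1 - C` with a top-down adaptive dendrogram cut: a
branch splits into its two children whenever both hold at least
`min_cluster_size` leaves, otherwise it becomes a cluster if large enough
and its genes are dropped if not. The cut is deterministic and
equivariant to gene order. This in-package cut plays the role of the
adaptive "dynamic" tree cut; the hybrid variant with per-branch
heterogeneity statistics is out of scope, so cluster counts on real data
will differ in detail from other implementations.

**Hypergraph.** Lifting expands each gene triplet over the Cartesian
product of its genes' module memberships (multi-membership duplicates
triplets deliberately); triplets touching an unassigned gene are dropped
and counted. Expected edge counts use sampling *without* replacement from
the pooled membership slots (`N` counts multi-membership duplicates,
since those inflate observed counts too):
`p(abc) = 6 na nb nc / (N(N-1)(N-2))`, `p(aab) = 3 na(na-1) nb / (...)`,
`p(aaa) = na(na-1)(na-2) / (...)`; these sum to one over all module
multisets, and a with-replacement variant is available behind a flag
(the two agree for large modules). Degree counts incident retained
hyperedges once per edge regardless of repeated labels; thresholding is
closed (`fold_change >= threshold`, ties kept); top-k ties break by label
order. The clique expansion writes each hyperedge as its distinct binary
edges (self-loops for repeated labels) for generic graph viewers.

## What the synthetic generator does and does not emulate

`generate_planted_dataset()` draws all genes i.i.d. standard normal except
planted triples, where `(x, y) | z` is bivariate normal with correlation
`delta * sign(z)` (closed-form population score `delta * sqrt(2/pi)`) or
`delta * tanh(z)`. Marginal pairwise correlations of a planted triple are
zero by symmetry, so the signal is invisible to pairwise screens — exactly
the structure the scan is meant to find. The generator does *not* emulate
RNA-seq count noise, library-size effects, or correlated background
structure between genes; since the pipeline operates on normal scores,
Gaussian fixtures exercise every stage, but passing tests demonstrate
correctness of the machinery, not performance on real transcriptomes,
where widespread nonzero pairwise correlation makes the screen (and hence
`c`) genuinely restrictive.

In the recovery tests the screen constant is set to `c = 3`: with
independent marginals the screen's scientific role (excluding truly
correlated pairs) is vacuous, and a tight screen would discard planted
triplets by pure sampling noise in the pair correlations (at `c = 2`
roughly one planted triple in seven loses eligibility), conflating screen
randomness with selection quality.

## Problem sizes used by the tests

The suite runs at desk scale by design: oracle comparisons at 20 genes,
null calibration on 50 replicates of 40 genes by 200 samples, planted
recovery with 100 genes, 200 samples and 20 planted triplets, hypergraph
calibration with 10,000 lifted triples over 4 modules of 25 genes, and
clustering recovery with two 30-gene blocks. Transcriptome-scale corpora
(tens of thousands of genes, hundreds of millions of selected triplets)
are cluster-scale workloads; the engine processes scouts independently in
bounded memory, and the pipeline exposes `genes_subset` and
`top_variance` to bound desk runs.

## Known limitations

* The local fdr is estimated, not exact; with very few eligible pairs per
  scout the curve is skipped (fewer than 10 observed or null values).
* Only the `E(XYZ)` form of Liquid Association is implemented; estimators
  based on conditional-correlation smoothing are out of scope, as are GO
  enrichment of clusters (cluster gene lists are exported instead) and
  styled figure rendering.
* The unsupervised cut drops genes on undersized branches rather than
  force-merging them; module counts are therefore sensitive to
  `min_cluster_size`.
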