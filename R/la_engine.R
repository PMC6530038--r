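# Liquid Association scan: for every scouting gene z, compute the triple
# product mean over all eligible (x, y) pairs. All functions assume rows
# have already been normal-score transformed.

#' Liquid Association score of a gene triplet
#'
#' The sample triple product mean `mean(x * y * z)`. For normal-score
#' transformed rows with near-zero mutual correlations this estimates the
#' expected change of the (x, y) correlation with the level of z. The score
#' is symmetric in its three arguments.
#'
#' @param x,y,z Numeric vectors of equal length (expression of three genes
#'   across the same samples).
#' @return A single number.
#' @examples
#' la_score(c(1, -1), c(1, -1), c(1, 1))  # 1
#' @export
la_score <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("x, y, z must have equal length")
  }
  if (length(x) < 1L) stop("empty vectors")
  mean(x * y * z)
}

#' Enumerate eligible pairs for a scouting gene
#'
#' Yields all pairs `(i, j)` with `i < j`, both different from `scout`, such
#' that all three pairs `(i, j)`, `(i, scout)`, `(j, scout)` are eligible
#' under the screening mask. Order is lexicographic in `(i, j)` so scans are
#' reproducible.
#'
#' @param scout Gene index (1-based row of the mask).
#' @param mask Symmetric logical eligibility matrix from [eligible_pairs()].
#' @return An integer matrix with columns `i`, `j` (possibly 0 rows).
#' @export
enumerate_scout_pairs <- function(scout, mask) {
  stopifnot(is.matrix(mask), is.logical(mask), nrow(mask) == ncol(mask))
  n <- nrow(mask)
  if (!is.numeric(scout) || length(scout) != 1L || scout < 1L || scout > n) {
    stop("scout index out of range")
  }
  scout <- as.integer(scout)
  cand <- which(mask[scout, ])
  cand <- cand[cand != scout]
  if (length(cand) < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  sub <- mask[cand, cand, drop = FALSE]
  idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
  out <- cbind(i = cand[idx[, 1L]], j = cand[idx[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Triple product means of the scout row z against precomputed elementwise
# pair products (rows of `prod_rows`); shared by observed and permuted scans.
scout_lambdas <- function(prod_rows, z) {
  as.vector(prod_rows %*% z) / length(z)
}

#' Scan one scouting gene
#'
#' Computes the Liquid Association score of the scout against every eligible
#' `(i, j)` pair. The returned lambda values form the observed per-scout
#' score distribution.
#'
#' @param x Transformed genes-by-samples matrix.
#' @param scout Gene index.
#' @param mask Eligibility mask from [eligible_pairs()].
#' @return A list of class `scout_scan`: `scout`, `pairs` (integer matrix),
#'   `lam` (numeric vector, one score per pair).
#' @export
scan_scout <- function(x, scout, mask) {
  stopifnot(is.matrix(x), nrow(x) == nrow(mask))
  pairs <- enumerate_scout_pairs(scout, mask)
  if (nrow(pairs) == 0L) {
    warning(sprintf("scout %d has no eligible pairs; skipped", scout))
    return(structure(list(scout = as.integer(scout), pairs = pairs,
                          lam = numeric(0)), class = "scout_scan"))
  }
  prod_rows <- x[pairs[, 1L], , drop = FALSE] * x[pairs[, 2L], , drop = FALSE]
  lam <- scout_lambdas(prod_rows, x[scout, ])
  structure(list(scout = as.integer(scout), pairs = pairs, lam = lam),
            class = "scout_scan")
}

# Canonicalize (i, j, scout) triples to sorted (i < j < k) rows.
canonical_triplets <- function(i, j, k) {
  t(apply(cbind(i, j, k), 1L, sort.int))
}
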