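# Per-scout permutation null, kernel density estimates, local-fdr curve
# and triplet selection.

#' Permutation null scan for one scouting gene
#'
#' Shuffles the sample order of the scout row and recomputes the Liquid
#' Association scores over the SAME eligible pair set as the observed scan
#' (eligibility is intentionally not recomputed: permuting the scout breaks
#' its ternary relations but must not change the pair universe being
#' compared). Values are pooled across permutations. Because each
#' permutation already yields one null score per eligible pair, a single
#' permutation usually gives thousands of null draws; more permutations are
#' useful only for small pair sets.
#'
#' @param x Transformed genes-by-samples matrix.
#' @param scout Gene index.
#' @param mask Eligibility mask from [eligible_pairs()].
#' @param n_permutations Number of independent shuffles to pool (default 1).
#' @param seed Integer seed; the permutation stream is fully determined by
#'   it.
#' @param permutations Optional list of explicit permutations of
#'   `1:ncol(x)`, overriding random generation (used for exact testing).
#' @return A list of class `null_model`: `scout`, `null_lams`,
#'   `n_permutations`, `seed`.
#' @export
permuted_scan <- function(x, scout, mask, n_permutations = 1L, seed = 1L,
                          permutations = NULL) {
  stopifnot(is.matrix(x), nrow(x) == nrow(mask), n_permutations >= 1L)
  pairs <- enumerate_scout_pairs(scout, mask)
  if (nrow(pairs) == 0L) {
    warning(sprintf("scout %d has no eligible pairs; empty null", scout))
    return(structure(list(scout = as.integer(scout), null_lams = numeric(0),
                          n_permutations = as.integer(n_permutations),
                          seed = as.integer(seed)), class = "null_model"))
  }
  m <- ncol(x)
  if (is.null(permutations)) {
    set.seed(as.integer(seed))
    permutations <- lapply(seq_len(n_permutations), function(b) sample.int(m))
  } else {
    n_permutations <- length(permutations)
  }
  prod_rows <- x[pairs[, 1L], , drop = FALSE] * x[pairs[, 2L], , drop = FALSE]
  z <- x[scout, ]
  null_lams <- unlist(lapply(permutations, function(p) {
    scout_lambdas(prod_rows, z[p])
  }), use.names = FALSE)
  structure(list(scout = as.integer(scout), null_lams = null_lams,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)), class = "null_model")
}

#' Gaussian kernel density estimate on a grid
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated at
#' the supplied grid points. For an equally spaced grid the FFT-based
#' estimator of [stats::density()] is used; otherwise the kernel sum is
#' evaluated directly.
#'
#' @param values Numeric sample, at least 10 values, not all identical.
#' @param grid Ordered numeric evaluation points.
#' @return Numeric vector of density estimates, one per grid point.
#' @export
kde_density <- function(values, grid) {
  stopifnot(is.numeric(values), is.numeric(grid), length(grid) >= 2L)
  if (length(values) < 10L) stop("need at least 10 values for a density estimate")
  if (stats::sd(values) == 0) stop("all values identical: bandwidth would be zero")
  h <- stats::bw.nrd0(values)
  steps <- diff(grid)
  if (all(abs(steps - steps[1L]) < 1e-9 * max(abs(steps)))) {
    d <- stats::density(values, bw = h, from = grid[1L],
                        to = grid[length(grid)], n = length(grid))
    d$y
  } else {
    vapply(grid, function(g) mean(stats::dnorm((g - values) / h)) / h,
           numeric(1))
  }
}

# Enforce monotone non-increasing fdr moving outward from the null mode by
# replacing each tail value with the maximum of all values further out
# (minimal non-increasing majorant). Never decreases any value, so a
# threshold appears only where the entire outward tail stays below target.
regularize_fdr <- function(fdr, mode_idx) {
  g <- length(fdr)
  out <- fdr
  if (mode_idx < g) out[mode_idx:g] <- rev(cummax(rev(fdr[mode_idx:g])))
  if (mode_idx > 1L) out[1:mode_idx] <- cummax(fdr[1:mode_idx])
  pmin(pmax(out, 0), 1)
}

#' Local false discovery rate curve for one scout
#'
#' Estimates the observed score density `f` and the permutation null
#' density `f0` on a common 512-point grid spanning the pooled sample range
#' plus three bandwidths, and forms the local fdr `f0 / f`, capped at 1
#' (with a floor of 1e-10 on `f` against division blow-ups).
#'
#' Scores of null triplets are approximately normal, and permutation draws
#' from different pairs share one null shape, so the default null density
#' is an envelope: the pointwise maximum of the kernel estimate of the
#' permutation sample and a normal fit to it (`"envelope"`). The kernel
#' part represents genuine heavy-tail structure present in the permutation
#' draws (pairs differ in product variance); the normal fit carries the
#' tail smoothly through regions where a finite permutation sample has no
#' draws, where a raw kernel estimate would collapse and make the density
#' ratio dip spuriously. `"normal"` (parametric only) and `"kde"` (kernel
#' only) are kept for comparison. The observed density is always a
#' Gaussian-kernel estimate, since it is a mixture of the null and an
#' unknown signal component.
#'
#' The raw density ratio is noisy in sparse tails of `f`, so each tail is
#' regularized to be monotone non-increasing moving outward from the null
#' mode by taking the minimal non-increasing majorant (each value becomes
#' the maximum of all values further out; no value ever decreases). The
#' selection thresholds are the innermost grid points, on each side of the
#' null mode, at which the regularized fdr drops to the target — that is,
#' beyond which the whole tail stays at or below it.
#'
#' @param observed Numeric vector of observed scores for a scout.
#' @param null A `null_model` from [permuted_scan()], or a numeric vector of
#'   null scores (possibly pooled across scouts; see [la_select()]).
#' @param fdr_target Target local fdr in (0, 1) (e.g. 0.1).
#' @param n_grid Number of grid points (default 512).
#' @param null_density `"envelope"` (default), `"normal"` or `"kde"`.
#' @return An object of class `fdr_curve`: `grid`, `f_obs`, `f_null`,
#'   `fdr` (regularized), `fdr_raw`, `mode` (null mode location),
#'   `lower_threshold`, `upper_threshold` (NA when the target is never
#'   reached on that side), `fdr_target`.
#' @export
fdr_curve <- function(observed, null, fdr_target = 0.1, n_grid = 512L,
                      null_density = c("envelope", "normal", "kde")) {
  null_density <- match.arg(null_density)
  if (inherits(null, "null_model")) null <- null$null_lams
  stopifnot(is.numeric(observed), is.numeric(null))
  if (!is.numeric(fdr_target) || fdr_target <= 0 || fdr_target >= 1) {
    stop("fdr_target must be in (0, 1)")
  }
  if (length(observed) < 10L || length(null) < 10L) {
    stop("need at least 10 observed and 10 null values")
  }
  h <- max(stats::bw.nrd0(observed), stats::bw.nrd0(null))
  # The grid spans the observed scan (a threshold beyond the observed data
  # cannot select anything) plus three bandwidths of margin.
  obs_range <- range(observed)
  grid <- seq(obs_range[1L] - 3 * h, obs_range[2L] + 3 * h, length.out = n_grid)
  f_obs <- kde_density(observed, grid)
  f_norm <- stats::dnorm(grid, mean(null), stats::sd(null))
  f_null <- switch(null_density,
                   envelope = pmax(kde_density(null, grid), f_norm),
                   normal = f_norm,
                   kde = kde_density(null, grid))
  fdr_raw <- pmin(1, f_null / pmax(f_obs, 1e-10))
  mode_idx <- which.max(f_null)
  fdr <- regularize_fdr(fdr_raw, mode_idx)
  upper_idx <- which(fdr <= fdr_target & seq_along(grid) > mode_idx)
  lower_idx <- which(fdr <= fdr_target & seq_along(grid) < mode_idx)
  structure(list(grid = grid, f_obs = f_obs, f_null = f_null,
                 fdr = fdr, fdr_raw = fdr_raw, mode = grid[mode_idx],
                 lower_threshold = if (length(lower_idx)) grid[max(lower_idx)] else NA_real_,
                 upper_threshold = if (length(upper_idx)) grid[min(upper_idx)] else NA_real_,
                 fdr_target = fdr_target),
            class = "fdr_curve")
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("local fdr curve: null mode %.4f, target %.3g\n", x$mode, x$fdr_target))
  cat(sprintf("thresholds: lower %s, upper %s\n",
              format(x$lower_threshold, digits = 4),
              format(x$upper_threshold, digits = 4)))
  invisible(x)
}

#' Select significant triplets across scouts
#'
#' A triplet is selected for a scout when its score falls at or beyond that
#' scout's lower or upper fdr threshold (both tails: dynamic correlation is
#' signed). Selections are unioned over all scouts, canonicalized to
#' `i < j < k`, and deduplicated (the score is identical from every scout
#' of a triplet by the symmetry of the triple product).
#'
#' @param scans List of `scout_scan` objects, one per scout.
#' @param curves List of `fdr_curve` objects aligned with `scans` (entries
#'   may be NULL for scouts with no usable curve).
#' @param fdr_target Target local fdr (recorded in the result).
#' @return A data.frame with columns `i`, `j`, `k` (canonical gene
#'   indices), `lam`, and `scout` (the first scout that selected the
#'   triplet).
#' @export
select_triplets <- function(scans, curves, fdr_target = 0.1) {
  stopifnot(length(scans) == length(curves))
  rows <- vector("list", length(scans))
  for (s in seq_along(scans)) {
    scan <- scans[[s]]
    curve <- curves[[s]]
    if (is.null(scan) || is.null(curve) || length(scan$lam) == 0L) next
    lo <- curve$lower_threshold
    up <- curve$upper_threshold
    sel <- rep(FALSE, length(scan$lam))
    if (!is.na(lo)) sel <- sel | scan$lam <= lo
    if (!is.na(up)) sel <- sel | scan$lam >= up
    if (!any(sel)) next
    tri <- canonical_triplets(scan$pairs[sel, 1L], scan$pairs[sel, 2L],
                              rep(scan$scout, sum(sel)))
    rows[[s]] <- data.frame(i = tri[, 1L], j = tri[, 2L], k = tri[, 3L],
                            lam = scan$lam[sel], scout = scan$scout)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      lam = numeric(0), scout = integer(0))
  }
  key <- paste(out$i, out$j, out$k)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$i, out$j, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr_target") <- fdr_target
  out
}

#' Full Liquid Association selection over all scouting genes
#'
#' Runs the observed scan and the permutation null for every gene in turn,
#' forms a local-fdr curve per scout, and unions and deduplicates the
#' selected triplets. Per-scout permutation seeds are derived
#' deterministically from `seed` by mixing in the scout index.
#'
#' By default (`pool_null = TRUE`) the null values from all per-scout
#' permutation scans are pooled into one null sample used by every scout's
#' curve: the null score distribution does not change shape from scout to
#' scout, and a single permutation per scout is too sparse in its extreme
#' tail to estimate a density ratio there, whereas the pooled sample
#' represents the tail (including heavy-tailed pairs) with thousands of
#' draws. Set `pool_null = FALSE` for strictly per-scout null densities.
#'
#' @param x Transformed genes-by-samples matrix.
#' @param mask Eligibility mask from [eligible_pairs()].
#' @param fdr_target Target local fdr (default 0.1).
#' @param n_permutations Permutations pooled per scout (default 1).
#' @param seed Integer master seed.
#' @param null_density Null density model passed to [fdr_curve()].
#' @param pool_null Pool permutation draws across scouts for the null
#'   density (default TRUE).
#' @return A list of class `la_selection`: `triplets` (canonical
#'   data.frame as in [select_triplets()]), `scans`, `curves`, and
#'   `n_scanned` (raw per-scout record count before deduplication).
#' @export
la_select <- function(x, mask, fdr_target = 0.1, n_permutations = 1L,
                      seed = 1L, null_density = c("envelope", "normal", "kde"),
                      pool_null = TRUE) {
  null_density <- match.arg(null_density)
  n <- nrow(x)
  scans <- vector("list", n)
  nulls <- vector("list", n)
  curves <- vector("list", n)
  n_scanned <- 0L
  for (s in seq_len(n)) {
    scan <- suppressWarnings(scan_scout(x, s, mask))
    scans[[s]] <- scan
    n_scanned <- n_scanned + length(scan$lam)
    if (length(scan$lam) == 0L) next
    nulls[[s]] <- suppressWarnings(
      permuted_scan(x, s, mask, n_permutations = n_permutations,
                    seed = scout_seed(seed, s)))$null_lams
  }
  pooled_null <- if (pool_null) unlist(nulls, use.names = FALSE) else NULL
  for (s in seq_len(n)) {
    scan <- scans[[s]]
    if (length(scan$lam) < 10L) next
    null <- if (pool_null) pooled_null else nulls[[s]]
    if (length(null) < 10L) next
    curves[[s]] <- fdr_curve(scan$lam, null, fdr_target = fdr_target,
                             null_density = null_density)
  }
  triplets <- select_triplets(scans, curves, fdr_target = fdr_target)
  structure(list(triplets = triplets, scans = scans, curves = curves,
                 n_scanned = n_scanned),
            class = "la_selection")
}

# Deterministic per-scout seed below 2^31.
scout_seed <- function(seed, scout) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(scout) * 10007) %% 2147483629)
}

#' Write selected triplets as TSV
#'
#' One row per canonical triplet with gene identifiers and the Liquid
#' Association score.
#'
#' @param triplets Data.frame from [select_triplets()] (columns i, j, k,
#'   lam).
#' @param gene_ids Character vector mapping gene indices to identifiers.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_triplets_tsv <- function(triplets, gene_ids, path) {
  df <- data.frame(gene_i = gene_ids[triplets$i],
                   gene_j = gene_ids[triplets$j],
                   gene_k = gene_ids[triplets$k],
                   lambda = sprintf("%.10g", triplets$lam))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
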