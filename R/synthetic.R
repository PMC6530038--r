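# Synthetic expression matrices with known null structure and planted
# dynamic-correlation triplets, for testing every pipeline stage without
# external data.

#' Generate a pure-null expression matrix
#'
#' i.i.d. standard-normal entries; the pipeline operates on normal scores,
#' so Gaussian fixtures exercise it fully.
#'
#' @param n Number of genes (>= 3).
#' @param m Number of samples (>= 4).
#' @param seed Integer seed; the matrix is fully determined by
#'   `(n, m, seed)`.
#' @return Numeric matrix with gene ids `g0001, ...` and sample ids
#'   `s0001, ...`.
#' @export
generate_null_matrix <- function(n, m, seed = 1L) {
  stopifnot(n >= 3L, m >= 4L)
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
  dimnames(x) <- list(sprintf("g%04d", seq_len(n)), sprintf("s%04d", seq_len(m)))
  x
}

#' Specification of one planted dynamic-correlation triplet
#'
#' Describes a triple `(x, y, z)` in which the conditional correlation of
#' `(x, y)` given `z` is `delta * sign(z)` (or `delta * tanh(z)`), while
#' all marginal pairwise correlations are zero in expectation. For the
#' sign link the population Liquid Association score has the closed form
#' `delta * sqrt(2/pi)`; for the tanh link it is
#' `delta * E[Z tanh(Z)]`, evaluated numerically.
#'
#' @param x,y,z Distinct gene indices.
#' @param delta Conditional-correlation amplitude in (0, 1).
#' @param link `"sign"` (default) or `"tanh"`.
#' @return A list of class `planted_triplet_spec`.
#' @export
planted_triplet_spec <- function(x, y, z, delta = 0.8,
                                 link = c("sign", "tanh")) {
  link <- match.arg(link)
  idx <- c(x, y, z)
  if (anyDuplicated(idx)) stop("x, y, z must be distinct gene indices")
  if (!is.numeric(delta) || delta < 0 || delta >= 1) {
    stop("delta must be in [0, 1)")  # 0 gives a pure-null triple
  }
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                 delta = delta, link = link),
            class = "planted_triplet_spec")
}

# Population E(XYZ) = delta * E[Z * link(Z)] for Z ~ N(0,1).
population_lambda <- function(delta, link) {
  if (link == "sign") {
    delta * sqrt(2 / pi)          # E|Z| = sqrt(2/pi)
  } else {
    delta * stats::integrate(function(z) z * tanh(z) * stats::dnorm(z),
                             -Inf, Inf)$value
  }
}

#' Generate a dataset with planted dynamic-correlation triplets
#'
#' All genes are i.i.d. standard normal except the planted triples: there,
#' `z ~ N(0,1)` and, given `z`, `(x, y)` is bivariate normal with unit
#' variances and correlation `rho(z) = delta * link(z)`. By symmetry of the
#' link functions the marginal correlations of the triple are all zero, so
#' the planted signal is invisible to pairwise methods but carries a
#' nonzero population triple product mean.
#'
#' @param n Total number of genes.
#' @param m Number of samples.
#' @param specs List of [planted_triplet_spec()] objects with pairwise
#'   disjoint gene indices.
#' @param seed Integer seed.
#' @return A list: `matrix` (n x m, named like [generate_null_matrix()])
#'   and `truth` (data.frame with canonical indices `i`, `j`, `k`,
#'   `delta`, `link`, `population_lambda`).
#' @export
generate_planted_dataset <- function(n, m, specs, seed = 1L) {
  stopifnot(n >= 3L, m >= 4L, is.list(specs))
  all_idx <- unlist(lapply(specs, function(s) c(s$x, s$y, s$z)))
  if (anyDuplicated(all_idx)) stop("planted gene indices must be disjoint across specs")
  if (length(all_idx) && max(all_idx) > n) stop("planted gene index exceeds n")
  x <- generate_null_matrix(n, m, seed)
  truth <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      delta = numeric(0), link = character(0),
                      population_lambda = numeric(0))
  for (s in specs) {
    zv <- stats::rnorm(m)
    rho <- s$delta * switch(s$link, sign = sign(zv), tanh = tanh(zv))
    a <- stats::rnorm(m)
    b <- stats::rnorm(m)
    x[s$x, ] <- a
    x[s$y, ] <- rho * a + sqrt(1 - rho^2) * b
    x[s$z, ] <- zv
    tri <- sort(c(s$x, s$y, s$z))
    truth <- rbind(truth, data.frame(
      i = tri[1L], j = tri[2L], k = tri[3L], delta = s$delta, link = s$link,
      population_lambda = population_lambda(s$delta, s$link)))
  }
  list(matrix = x, truth = truth)
}

#' Recall and empirical FDR of a selection against planted truth
#'
#' @param selection Data.frame of selected canonical triplets (columns
#'   `i`, `j`, `k`).
#' @param truth Truth table from [generate_planted_dataset()].
#' @return A list: `recall` (planted triplets recovered / planted),
#'   `empirical_fdr` (non-planted selected / selected; 0 when nothing is
#'   selected), `n_selected`, `n_planted`.
#' @export
planted_recovery_report <- function(selection, truth) {
  sel_key <- paste(selection$i, selection$j, selection$k)
  truth_key <- paste(truth$i, truth$j, truth$k)
  n_sel <- length(sel_key)
  n_planted <- length(truth_key)
  hits <- sum(truth_key %in% sel_key)
  list(recall = if (n_planted) hits / n_planted else NA_real_,
       empirical_fdr = if (n_sel) sum(!(sel_key %in% truth_key)) / n_sel else 0,
       n_selected = n_sel, n_planted = n_planted)
}

#' Write a synthetic fixture to disk
#'
#' Emits the expression matrix as TSV (gene column first) plus a
#' truth-table TSV, the format consumed by the pipeline.
#'
#' @param dataset Result of [generate_planted_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the two file paths.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expression.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  df <- data.frame(gene = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(expression = expr_path, truth = truth_path))
}
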