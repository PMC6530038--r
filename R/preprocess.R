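#' Load an expression matrix from a delimited file
#'
#' Reads a genes-by-samples expression table with gene identifiers in the
#' first column and sample identifiers in the header, then drops genes whose
#' fraction of zero entries exceeds `max_zero_fraction`. Dropping
#' high-zero genes is standard practice for RNA-seq abundance matrices,
#' where genes with many zeros carry little correlation information and
#' destabilise the rank-based transform downstream.
#'
#' @param path Path to a TSV or CSV file. The delimiter is inferred from the
#'   file extension (`.csv` means comma, anything else tab) unless `sep` is
#'   given.
#' @param max_zero_fraction Maximum tolerated fraction of zero entries per
#'   gene, in `[0, 1]`. Default 0.10.
#' @param sep Optional explicit field delimiter overriding the
#'   extension-based guess.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names. The identifiers of
#'   dropped genes are attached as attribute `"dropped_genes"`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' write.table(data.frame(gene = rownames(m), m), tf,
#'             sep = "\t", quote = FALSE, row.names = FALSE)
#' x <- load_expression(tf)
#' dim(x)
#' @export
load_expression <- function(path, max_zero_fraction = 0.10, sep = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  if (!is.numeric(max_zero_fraction) || length(max_zero_fraction) != 1L ||
      is.na(max_zero_fraction) || max_zero_fraction < 0 || max_zero_fraction > 1) {
    stop("`max_zero_fraction` must be a single number in [0, 1]")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, na.strings = NULL)
  if (ncol(dt) < 2L) stop("expression file must have a gene column and at least one sample column")
  gene_ids <- as.character(dt[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1L]], gene_ids[bad[1L]], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- gene_ids
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(x)[bad[2L]]))
  }
  zero_frac <- rowMeans(x == 0)
  keep <- zero_frac <= max_zero_fraction
  message(sprintf("load_expression: %d genes kept, %d dropped (zero fraction > %.3g)",
                  sum(keep), sum(!keep), max_zero_fraction))
  out <- x[keep, , drop = FALSE]
  attr(out, "dropped_genes") <- gene_ids[!keep]
  out
}

#' Normal score (rank-based inverse normal) transform
#'
#' Maps each value to the standard normal quantile of its rank:
#' `qnorm(r / (m + 1))` with average ranks for ties (van der Waerden
#' scores). Applied row-wise when given a matrix. The transform makes each
#' gene marginally close to standard normal, a prerequisite for the triple
#' product mean to measure dynamic correlation.
#'
#' @param x A numeric vector (one gene across samples) or a genes-by-samples
#'   numeric matrix.
#' @return The transformed vector or matrix, same shape and dimnames.
#' @examples
#' normal_score_transform(c(10, 30, 20))
#' @export
normal_score_transform <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, normal_score_transform))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  m <- length(x)
  if (m < 2L) stop("normal score transform needs at least 2 values")
  if (anyNA(x)) stop("missing values are not allowed")
  if (all(x == x[1L])) stop("constant row: ranks (and hence normal scores) are undefined")
  r <- rank(x, ties.method = "average")
  stats::qnorm(r / (m + 1))
}

#' Summarise the pairwise-correlation screen
#'
#' Computes the mean `mu` and standard deviation `sigma` of the
#' `n(n-1)/2` distinct off-diagonal pairwise Pearson correlations of a
#' (transformed) expression matrix, and the open screening interval
#' `(mu - c*sigma, mu + c*sigma)`. Only gene pairs whose correlation falls
#' strictly inside this interval are admitted to the Liquid Association
#' scan: near-zero mutual correlation within a triplet is the sufficient
#' condition under which the triple product mean validly measures dynamic
#' correlation.
#'
#' @param x Transformed genes-by-samples numeric matrix with `n >= 2` rows.
#' @param c Non-negative screen width constant; `c = 0` gives a degenerate
#'   (empty) interval.
#' @return An object of class `screen_summary`: a list with `mu`, `sigma`,
#'   `c`, `lower`, `upper`.
#' @seealso [eligible_pairs()], [suggest_screen_constant()]
#' @export
screen_summary <- function(x, c = 0.5) {
  stopifnot(is.matrix(x), is.numeric(c), length(c) == 1L, c >= 0)
  if (nrow(x) < 2L) stop("need at least 2 genes to summarise pairwise correlations")
  r <- stats::cor(t(x))
  off <- r[upper.tri(r)]
  mu <- mean(off)
  sigma <- stats::sd(off)
  structure(list(mu = mu, sigma = sigma, c = c,
                 lower = mu - c * sigma, upper = mu + c * sigma),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("pairwise correlation screen: mu = %.4f, sigma = %.4f, c = %.3g\n",
              x$mu, x$sigma, x$c))
  cat(sprintf("open interval: (%.4f, %.4f)\n", x$lower, x$upper))
  invisible(x)
}

#' Pair eligibility mask under the correlation screen
#'
#' Marks the gene pairs whose Pearson correlation lies strictly inside the
#' screening interval of a [screen_summary()]. The mask is symmetric with a
#' `FALSE` diagonal; a triplet is admissible only if all three of its pairs
#' are eligible.
#'
#' @param x Transformed genes-by-samples matrix (the same matrix the summary
#'   was computed on).
#' @param summary A `screen_summary` object.
#' @return An `n x n` logical matrix with gene identifiers as dimnames.
#' @export
eligible_pairs <- function(x, summary) {
  stopifnot(is.matrix(x), inherits(summary, "screen_summary"))
  r <- stats::cor(t(x))
  mask <- r > summary$lower & r < summary$upper
  diag(mask) <- FALSE
  mask
}

#' Sampling standard deviation of a null Pearson correlation
#'
#' Large-sample (Fisher transformation) approximation `1/sqrt(m)` for the
#' standard deviation of the sample correlation between two truly
#' uncorrelated genes measured on `m` samples. Used to judge how wide the
#' correlation screen should be relative to pure sampling noise.
#'
#' @param m Number of samples, at least 4.
#' @return `1/sqrt(m)`.
#' @examples
#' correlation_sampling_sd(474)  # 0.046
#' correlation_sampling_sd(77)   # 0.114
#' @export
correlation_sampling_sd <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L)
  if (m < 4) stop("need at least 4 samples")
  1 / sqrt(m)
}

#' 95% confidence half-width of a null Pearson correlation
#'
#' `1.96/sqrt(m)`: half-width of the unadjusted 95% CI of the sample
#' correlation between two uncorrelated genes.
#'
#' @inheritParams correlation_sampling_sd
#' @return `1.96/sqrt(m)`.
#' @export
correlation_ci_halfwidth <- function(m) {
  1.96 * correlation_sampling_sd(m)
}

#' Suggest the screen constant c from sample size
#'
#' Returns the `c` for which the screening interval half-width
#' `c * sigma` equals the null 95% CI half-width `1.96/sqrt(m)`, so the
#' screen admits roughly the pairs whose correlation is indistinguishable
#' from zero.
#'
#' @param summary A `screen_summary` (only `sigma` is used).
#' @param m Number of samples.
#' @return Suggested value of `c`.
#' @export
suggest_screen_constant <- function(summary, m) {
  stopifnot(inherits(summary, "screen_summary"))
  correlation_ci_halfwidth(m) / summary$sigma
}
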