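# Gene-to-module assignment: supervised from a GMT gene-set collection, or
# unsupervised by clustering genes on their triplet co-involvement profiles.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated, fields are set name,
#' description, then member gene identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (set name -> member genes).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) stop("malformed GMT line (need name, description, >=1 gene): line ",
                       which(short)[1L])
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Supervised gene-to-module assignment from gene sets
#'
#' Filters the collection to sets whose size, after intersecting with the
#' genes present in the data, lies in `[min_set_size, max_set_size]`, then
#' maps each gene to every surviving set containing it. Multi-membership is
#' preserved (such genes later duplicate their triplets at lifting time);
#' genes in no surviving set are dropped from module-level analysis.
#'
#' @param genes Character vector of gene identifiers present in the data.
#' @param collection Named list of gene sets, e.g. from [read_gmt()].
#' @param min_set_size,max_set_size Inclusive size window applied after
#'   intersection with `genes`. Defaults 5 and 500, the usual window for
#'   informative functional categories.
#' @return An object of class `module_assignment`: `mode` ("supervised"),
#'   `membership` (named list gene -> character vector of module labels),
#'   `dropped` (genes with no module), `module_sizes` (named integer
#'   vector).
#' @export
assign_supervised <- function(genes, collection, min_set_size = 5L,
                              max_set_size = 500L) {
  stopifnot(is.character(genes), length(genes) > 0L)
  if (!is.list(collection) || length(collection) == 0L) {
    stop("empty gene-set collection")
  }
  inter <- lapply(collection, function(s) intersect(s, genes))
  sz <- lengths(inter)
  keep <- sz >= min_set_size & sz <= max_set_size
  if (!any(keep)) {
    stop(sprintf("no gene set has between %d and %d genes after intersection with the data",
                 min_set_size, max_set_size))
  }
  inter <- inter[keep]
  membership <- vector("list", length(genes))
  names(membership) <- genes
  for (set in names(inter)) {
    for (g in inter[[set]]) membership[[g]] <- c(membership[[g]], set)
  }
  has <- !vapply(membership, is.null, logical(1))
  structure(list(mode = "supervised",
                 membership = membership[has],
                 dropped = genes[!has],
                 module_sizes = vapply(inter, length, integer(1))),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("%s module assignment: %d genes in %d modules, %d dropped\n",
              x$mode, length(x$membership), length(x$module_sizes),
              length(x$dropped)))
  invisible(x)
}

#' Pair co-involvement count matrix
#'
#' Builds the symmetric `n x n` matrix `A` tallying, for every gene pair,
#' how many selected triplets contain both genes: each triplet `(i, j, k)`
#' increments the six ordered cells `(i,j), (j,i), (i,k), (k,i), (j,k),
#' (k,j)` by one. The diagonal is zero, so the grand total is six times the
#' number of triplets.
#'
#' @param triplets Data.frame or matrix with integer columns `i`, `j`, `k`
#'   (canonical, deduplicated).
#' @param n Number of genes (matrix dimension).
#' @return An `n x n` integer matrix.
#' @export
build_pair_count_matrix <- function(triplets, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1L)
  tri <- as.matrix(as.data.frame(triplets)[, c("i", "j", "k")])
  if (nrow(tri) == 0L) return(matrix(0L, n, n))
  if (any(tri < 1L) || any(tri > n)) stop("triplet gene index out of range 1..n")
  a <- c(tri[, 1L], tri[, 2L], tri[, 1L], tri[, 3L], tri[, 2L], tri[, 3L])
  b <- c(tri[, 2L], tri[, 1L], tri[, 3L], tri[, 1L], tri[, 3L], tri[, 2L])
  counts <- tabulate((a - 1L) * n + b, nbins = n * n)
  matrix(as.integer(counts), n, n)
}

#' Distance between triplet co-involvement profiles
#'
#' Correlates the rows of the pair count matrix `A` (each row is a gene's
#' profile of co-involvement with every other gene) and returns the
#' distance `D = 1 - C`. Genes appearing in no triplet (all-zero rows) have
#' an undefined correlation and are excluded; their identifiers are
#' reported in attribute `"excluded"`.
#'
#' @param A Pair count matrix from [build_pair_count_matrix()]; row names,
#'   if present, are carried through.
#' @return Distance matrix `D` over the clusterable genes, with attributes
#'   `"excluded"` (indices or names of all-zero rows) and `"kept"` (row
#'   indices retained).
#' @export
pair_profile_distance <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  keep <- which(rowSums(A != 0) > 0L)
  if (length(keep) < 2L) stop("fewer than 2 genes with any triplet involvement")
  C <- stats::cor(t(A[keep, , drop = FALSE]))
  D <- 1 - C
  diag(D) <- 0
  D <- (D + t(D)) / 2
  ids <- rownames(A)
  dn <- if (is.null(ids)) as.character(keep) else ids[keep]
  dimnames(D) <- list(dn, dn)
  attr(D, "excluded") <- if (is.null(ids)) setdiff(seq_len(nrow(A)), keep) else ids[-keep]
  attr(D, "kept") <- keep
  D
}

# Members (leaf indices) of every internal node of an hclust merge tree.
hclust_node_members <- function(merge) {
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) {
    kids <- merge[v, ]
    members[[v]] <- c(if (kids[1L] < 0) -kids[1L] else members[[kids[1L]]],
                      if (kids[2L] < 0) -kids[2L] else members[[kids[2L]]])
  }
  members
}

#' Unsupervised gene grouping by adaptive dendrogram decomposition
#'
#' Average-linkage hierarchical clustering on the co-involvement distance
#' matrix, cut by a top-down adaptive branch decomposition honouring a
#' minimum cluster size: starting from the root, a branch is split into its
#' two children whenever both children contain at least `min_cluster_size`
#' leaves; otherwise the branch becomes a cluster if it is large enough,
#' and its genes are dropped if not. The procedure is deterministic: no
#' randomness enters the linkage or the cut.
#'
#' @param D Distance matrix from [pair_profile_distance()].
#' @param min_cluster_size Minimum genes per cluster, at least 2.
#' @return A `module_assignment` with `mode = "unsupervised"`: every
#'   clustered gene has exactly one label (`C1`, `C2`, ... in decreasing
#'   cluster size).
#' @export
cluster_unsupervised <- function(D, min_cluster_size = 20L) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!is.numeric(min_cluster_size) || min_cluster_size < 2L) {
    stop("min_cluster_size must be at least 2")
  }
  n <- nrow(D)
  if (min_cluster_size > n) {
    stop(sprintf("min_cluster_size (%d) exceeds the number of clusterable genes (%d)",
                 min_cluster_size, n))
  }
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  members <- hclust_node_members(hc$merge)
  clusters <- list()
  dropped_leaves <- integer(0)
  # iterative depth-first decomposition from the root
  stack <- nrow(hc$merge)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v < 0) {            # single leaf: never a cluster on its own
      dropped_leaves <- c(dropped_leaves, -v)
      next
    }
    kids <- hc$merge[v, ]
    size_of <- function(k) if (k < 0) 1L else length(members[[k]])
    if (size_of(kids[1L]) >= min_cluster_size &&
        size_of(kids[2L]) >= min_cluster_size) {
      stack <- c(kids[1L], kids[2L], stack)
    } else if (length(members[[v]]) >= min_cluster_size) {
      clusters[[length(clusters) + 1L]] <- members[[v]]
    } else {
      dropped_leaves <- c(dropped_leaves, members[[v]])
    }
  }
  if (!length(clusters)) stop("no branch reaches min_cluster_size")
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]
  labels <- paste0("C", seq_along(clusters))
  membership <- list()
  for (ci in seq_along(clusters)) {
    for (leaf in clusters[[ci]]) membership[[ids[leaf]]] <- labels[ci]
  }
  membership <- membership[order(match(names(membership), ids))]
  structure(list(mode = "unsupervised",
                 membership = lapply(membership, identity),
                 dropped = ids[sort(dropped_leaves)],
                 module_sizes = stats::setNames(lengths(clusters), labels)),
            class = "module_assignment")
}

#' Write a module assignment as two-column TSV
#'
#' One row per (gene, module) membership.
#'
#' @param assignment A `module_assignment`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_modules_tsv <- function(assignment, path) {
  stopifnot(inherits(assignment, "module_assignment"))
  genes <- rep(names(assignment$membership),
               lengths(assignment$membership))
  df <- data.frame(gene = genes,
                   module = unlist(assignment$membership, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
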