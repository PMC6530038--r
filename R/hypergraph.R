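# Lift selected gene triplets to module labels and aggregate them into a
# weighted 3-uniform hypergraph with fold-change edge weights.

#' Lift gene triplets to module-label triples
#'
#' Replaces each gene of a triplet by its module label(s). A gene carrying
#' several module labels duplicates the triplet once per label combination
#' (the Cartesian product of the three membership lists), preserving
#' multi-functional information. Triplets containing any gene without a
#' module are discarded; their number is attached as attribute
#' `"n_discarded"`.
#'
#' @param triplets Data.frame with integer columns `i`, `j`, `k` (canonical
#'   gene indices).
#' @param assignment A `module_assignment`.
#' @param gene_ids Character vector mapping gene indices to the identifiers
#'   used in `assignment`.
#' @return A character matrix with 3 columns, one row per lifted triple,
#'   each row sorted (unordered multiset representation).
#' @export
lift_triplets <- function(triplets, assignment, gene_ids) {
  stopifnot(inherits(assignment, "module_assignment"), is.character(gene_ids))
  tri <- as.data.frame(triplets)[, c("i", "j", "k")]
  memb <- assignment$membership
  rows <- vector("list", nrow(tri))
  n_discarded <- 0L
  for (r in seq_len(nrow(tri))) {
    m1 <- memb[[gene_ids[tri$i[r]]]]
    m2 <- memb[[gene_ids[tri$j[r]]]]
    m3 <- memb[[gene_ids[tri$k[r]]]]
    if (is.null(m1) || is.null(m2) || is.null(m3)) {
      n_discarded <- n_discarded + 1L
      next
    }
    combo <- expand.grid(a = m1, b = m2, c = m3,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    rows[[r]] <- t(apply(as.matrix(combo), 1L, sort))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(character(0), ncol = 3L)
  colnames(out) <- c("m1", "m2", "m3")
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Edge type of a module multiset
#'
#' Number of distinct module labels among the three: 1 (self-loop on one
#' module), 2 (two modules, one repeated) or 3 (three distinct modules).
#'
#' @param modules Character or numeric vector of exactly 3 labels.
#' @return Integer 1, 2 or 3.
#' @export
classify_edge_type <- function(modules) {
  if (length(modules) != 3L) stop("a hyperedge has exactly 3 module labels")
  length(unique(modules))
}

#' Expected triplet count of a module hyperedge under random placement
#'
#' Probability that a random gene triple falls in the given module multiset
#' times the total number of lifted triples. The default model draws the
#' three genes without replacement from the pooled membership slots
#' (`N = sum(module_sizes)`, counting multi-membership duplicates):
#' `p(abc) = 6 na nb nc / (N(N-1)(N-2))`,
#' `p(aab) = 3 na(na-1) nb / (N(N-1)(N-2))`,
#' `p(aaa) = na(na-1)(na-2) / (N(N-1)(N-2))`.
#' These probabilities sum to one over all module multisets. The
#' `"with"` model replaces falling factorials by plain powers of `N`
#' (sampling with replacement); the two agree for large modules.
#'
#' @param modules Vector of exactly 3 module labels (repeats allowed).
#' @param module_sizes Named vector of module gene counts.
#' @param total_lifted Total number of lifted gene triples.
#' @param model `"without"` (default) or `"with"` replacement.
#' @return Expected count (a positive real).
#' @export
expected_count <- function(modules, module_sizes, total_lifted,
                           model = c("without", "with")) {
  model <- match.arg(model)
  if (length(modules) != 3L) stop("a hyperedge has exactly 3 module labels")
  if (!all(as.character(modules) %in% names(module_sizes))) {
    stop("unknown module label in hyperedge")
  }
  sz <- module_sizes[as.character(modules)]
  if (any(sz < 1)) stop("referenced module has size 0")
  N <- sum(module_sizes)
  if (N < 3) stop("need at least 3 membership slots in total")
  tab <- table(as.character(modules))
  p <- if (model == "without") {
    denom <- N * (N - 1) * (N - 2)
    if (length(tab) == 3L) {
      6 * prod(module_sizes[names(tab)]) / denom
    } else if (length(tab) == 2L) {
      a <- names(tab)[tab == 2L]
      b <- names(tab)[tab == 1L]
      3 * module_sizes[[a]] * (module_sizes[[a]] - 1) * module_sizes[[b]] / denom
    } else {
      a <- names(tab)[1L]
      module_sizes[[a]] * (module_sizes[[a]] - 1) * (module_sizes[[a]] - 2) / denom
    }
  } else {
    denom <- N^3
    coef <- c(`1` = 1, `2` = 3, `3` = 6)[[as.character(length(tab))]]
    coef * prod(module_sizes[names(tab)]^as.integer(tab)) / denom
  }
  unname(total_lifted * p)
}

#' Build the module-level 3-uniform hypergraph
#'
#' Aggregates identical lifted module triples into hyperedges whose weight
#' is the observed count, and annotates each edge with its expected count
#' under random placement, the fold change (count / expected), and the
#' edge type. Self-loops (repeated labels) are allowed. The sum of edge
#' counts equals the number of lifted triples.
#'
#' @param lifted Character matrix from [lift_triplets()] (rows sorted).
#' @param assignment The `module_assignment` used for lifting (supplies
#'   module sizes).
#' @param model Random-placement model for [expected_count()].
#' @return An object of class `la_hypergraph`: `vertices` (data.frame
#'   `module`, `size`), `edges` (data.frame `m1`, `m2`, `m3`, `count`,
#'   `expected`, `fold_change`, `edge_type`), `total_lifted`, `model`.
#' @export
build_hypergraph <- function(lifted, assignment, model = c("without", "with")) {
  model <- match.arg(model)
  stopifnot(inherits(assignment, "module_assignment"))
  lifted <- as.matrix(lifted)
  if (nrow(lifted) == 0L) stop("no lifted triples: cannot build a hypergraph")
  sizes <- assignment$module_sizes
  key <- paste(lifted[, 1L], lifted[, 2L], lifted[, 3L], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(m1 = vapply(parts, `[[`, character(1), 1L),
                      m2 = vapply(parts, `[[`, character(1), 2L),
                      m3 = vapply(parts, `[[`, character(1), 3L),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
  edges$expected <- vapply(seq_len(nrow(edges)), function(r) {
    expected_count(c(edges$m1[r], edges$m2[r], edges$m3[r]), sizes,
                   nrow(lifted), model = model)
  }, numeric(1))
  edges$fold_change <- edges$count / edges$expected
  edges$edge_type <- vapply(seq_len(nrow(edges)), function(r) {
    classify_edge_type(c(edges$m1[r], edges$m2[r], edges$m3[r]))
  }, integer(1))
  edges <- edges[order(edges$m1, edges$m2, edges$m3), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = data.frame(module = names(sizes),
                                       size = as.integer(sizes),
                                       stringsAsFactors = FALSE),
                 edges = edges,
                 total_lifted = nrow(lifted),
                 model = model),
            class = "la_hypergraph")
}

#' @export
print.la_hypergraph <- function(x, ...) {
  cat(sprintf("3-uniform module hypergraph: %d vertices, %d hyperedges, %d lifted triples\n",
              nrow(x$vertices), nrow(x$edges), x$total_lifted))
  if (!is.null(x$median_degree)) {
    cat(sprintf("median vertex degree: %g\n", x$median_degree))
  }
  invisible(x)
}

#' Vertex degrees of a module hypergraph
#'
#' Degree of a vertex = number of incident hyperedges, counted once per
#' edge regardless of how many of the edge's three slots the module fills.
#'
#' @param graph An `la_hypergraph`.
#' @return Named integer vector over the graph's vertices.
#' @export
vertex_degrees <- function(graph) {
  stopifnot(inherits(graph, "la_hypergraph"))
  deg <- stats::setNames(integer(nrow(graph$vertices)), graph$vertices$module)
  for (r in seq_len(nrow(graph$edges))) {
    for (v in unique(c(graph$edges$m1[r], graph$edges$m2[r], graph$edges$m3[r]))) {
      deg[[v]] <- deg[[v]] + 1L
    }
  }
  deg
}

#' Threshold hyperedges by fold change
#'
#' Keeps edges with `fold_change >= min_fold_change` (closed threshold,
#' ties kept) and removes vertices left with no incident edge. The median
#' vertex degree of the thresholded graph is stored in `median_degree`.
#'
#' @param graph An `la_hypergraph`.
#' @param min_fold_change Non-negative threshold; 0 keeps everything.
#' @return The thresholded `la_hypergraph` (vertices gain a `degree`
#'   column).
#' @export
threshold_edges <- function(graph, min_fold_change = 0) {
  stopifnot(inherits(graph, "la_hypergraph"), min_fold_change >= 0)
  out <- graph
  out$edges <- graph$edges[graph$edges$fold_change >= min_fold_change, ,
                           drop = FALSE]
  rownames(out$edges) <- NULL
  touched <- unique(c(out$edges$m1, out$edges$m2, out$edges$m3))
  out$vertices <- graph$vertices[graph$vertices$module %in% touched, ,
                                 drop = FALSE]
  rownames(out$vertices) <- NULL
  deg <- vertex_degrees(out)
  out$vertices$degree <- as.integer(deg[out$vertices$module])
  out$median_degree <- if (nrow(out$vertices)) stats::median(out$vertices$degree) else NA_real_
  out
}

#' Suggest a fold-change threshold for a target median degree
#'
#' Scans the candidate thresholds (0 and every observed fold change,
#' ascending) and returns the smallest at which the median vertex degree of
#' the thresholded graph drops to `target_median_degree` or below. A median
#' degree of about 4 with hundreds of modules, or about 20 with tens of
#' modules, gives graphs sparse enough for visual inspection.
#'
#' @param graph An `la_hypergraph` (unthresholded).
#' @param target_median_degree Desired upper bound on the median degree.
#' @return The suggested threshold, or `NA` if no candidate achieves it.
#' @export
suggest_threshold <- function(graph, target_median_degree) {
  stopifnot(inherits(graph, "la_hypergraph"), target_median_degree >= 0)
  cands <- sort(unique(c(0, graph$edges$fold_change)))
  for (t in cands) {
    g <- threshold_edges(graph, t)
    if (nrow(g$vertices) == 0L) return(NA_real_)
    if (g$median_degree <= target_median_degree) return(t)
  }
  NA_real_
}

#' Ego sub-hypergraph of a vertex
#'
#' All hyperedges incident to the given module, together with every module
#' they touch.
#'
#' @param graph An `la_hypergraph`.
#' @param vertex Module label.
#' @return An `la_hypergraph` restricted to the ego neighbourhood.
#' @export
ego_subhypergraph <- function(graph, vertex) {
  stopifnot(inherits(graph, "la_hypergraph"))
  if (!vertex %in% graph$vertices$module) stop("unknown vertex: ", vertex)
  inc <- graph$edges$m1 == vertex | graph$edges$m2 == vertex |
    graph$edges$m3 == vertex
  out <- graph
  out$edges <- graph$edges[inc, , drop = FALSE]
  rownames(out$edges) <- NULL
  touched <- unique(c(vertex, out$edges$m1, out$edges$m2, out$edges$m3))
  out$vertices <- graph$vertices[graph$vertices$module %in% touched, ,
                                 drop = FALSE]
  rownames(out$vertices) <- NULL
  out
}

#' Sub-hypergraph of the k most connected vertices
#'
#' Selects the `k` highest-degree modules (ties broken by label order) and
#' keeps the hyperedges whose three slots all lie within that set.
#'
#' @param graph An `la_hypergraph`.
#' @param k Number of vertices, at least 1.
#' @return An `la_hypergraph` on the top-`k` vertex set.
#' @export
top_k_subhypergraph <- function(graph, k) {
  stopifnot(inherits(graph, "la_hypergraph"), k >= 1L)
  deg <- vertex_degrees(graph)
  ord <- order(-deg, names(deg))
  top <- names(deg)[ord][seq_len(min(k, length(deg)))]
  keep <- graph$edges$m1 %in% top & graph$edges$m2 %in% top &
    graph$edges$m3 %in% top
  out <- graph
  out$edges <- graph$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$vertices <- graph$vertices[graph$vertices$module %in% top, , drop = FALSE]
  rownames(out$vertices) <- NULL
  out
}

#' Gene-level sub-hypergraph of one module hyperedge
#'
#' Returns the selected gene triplets that lift to exactly the given module
#' multiset, as a gene-level hypergraph: vertices are genes with size equal
#' to their incident edge count; each gene triplet is an edge whose count
#' is the number of its label combinations matching the multiset (a gene
#' triplet with multi-membership genes can match more than once). The sum
#' of edge counts equals the parent hyperedge's count.
#'
#' @param triplets Data.frame with columns `i`, `j`, `k`.
#' @param assignment The `module_assignment` used for lifting.
#' @param gene_ids Gene identifier vector (index -> id).
#' @param module_triple Character vector of 3 module labels.
#' @return A list of class `gene_hypergraph`: `vertices` (data.frame
#'   `gene`, `size`), `edges` (data.frame `gene_a`, `gene_b`, `gene_c`,
#'   `count`, `edge_type`), `module_triple`.
#' @export
gene_level_subhypergraph <- function(triplets, assignment, gene_ids,
                                     module_triple) {
  stopifnot(length(module_triple) == 3L)
  target <- unname(sort(as.character(module_triple)))
  tri <- as.data.frame(triplets)[, c("i", "j", "k")]
  memb <- assignment$membership
  rows <- list()
  for (r in seq_len(nrow(tri))) {
    ids <- gene_ids[c(tri$i[r], tri$j[r], tri$k[r])]
    ms <- lapply(ids, function(g) memb[[g]])
    if (any(vapply(ms, is.null, logical(1)))) next
    combo <- expand.grid(a = ms[[1L]], b = ms[[2L]], c = ms[[3L]],
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    mult <- sum(apply(as.matrix(combo), 1L,
                      function(v) identical(unname(sort(v)), target)))
    if (mult > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ids[1L], gene_b = ids[2L], gene_c = ids[3L],
        count = mult, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("module triple is not an edge of the lifted hypergraph")
  edges <- do.call(rbind, rows)
  edges$edge_type <- classify_edge_type(target)
  genes <- unique(c(edges$gene_a, edges$gene_b, edges$gene_c))
  size <- vapply(genes, function(g) {
    sum(edges$gene_a == g | edges$gene_b == g | edges$gene_c == g)
  }, integer(1))
  structure(list(vertices = data.frame(gene = genes, size = as.integer(size),
                                       stringsAsFactors = FALSE),
                 edges = edges, module_triple = target),
            class = "gene_hypergraph")
}

#' Clique expansion of a module hypergraph
#'
#' Reduces each hyperedge to its distinct binary edges for generic graph
#' viewers: a type-3 edge gives three pairwise edges, a type-2 edge gives
#' one self-loop plus one pairwise edge, a type-1 edge gives a single
#' self-loop. Edge weight is the fold change.
#'
#' @param graph An `la_hypergraph`.
#' @return A data.frame with columns `from`, `to`, `weight`, `count`,
#'   `edge_type`.
#' @export
clique_expansion <- function(graph) {
  stopifnot(inherits(graph, "la_hypergraph"))
  rows <- lapply(seq_len(nrow(graph$edges)), function(r) {
    e <- graph$edges[r, ]
    labs <- c(e$m1, e$m2, e$m3)
    prs <- unique(t(utils::combn(labs, 2L)))
    prs <- prs[!duplicated(paste(pmin(prs[, 1L], prs[, 2L]),
                                 pmax(prs[, 1L], prs[, 2L]))), , drop = FALSE]
    data.frame(from = prs[, 1L], to = prs[, 2L], weight = e$fold_change,
               count = e$count, edge_type = e$edge_type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), count = integer(0),
                      edge_type = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Export the clique expansion as GraphML
#'
#' Writes the binary-edge reduction with vertex attributes (module size
#' and, when present, degree) and edge weight equal to the fold change.
#'
#' @param graph An `la_hypergraph`.
#' @param path Output `.graphml` path.
#' @return The path, invisibly.
#' @export
write_hypergraph_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "la_hypergraph"))
  ce <- clique_expansion(graph)
  vdf <- graph$vertices
  names(vdf)[1L] <- "name"
  g <- igraph::graph_from_data_frame(ce, directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write hyperedges as TSV
#'
#' One row per hyperedge: the three sorted module labels, count, expected
#' count, fold change and edge type.
#'
#' @param graph An `la_hypergraph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hyperedges_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "la_hypergraph"))
  e <- graph$edges
  df <- data.frame(module_a = e$m1, module_b = e$m2, module_c = e$m3,
                   count = e$count,
                   expected = sprintf("%.10g", e$expected),
                   fold_change = sprintf("%.10g", e$fold_change),
                   edge_type = e$edge_type)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
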