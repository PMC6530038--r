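# End-to-end orchestration: preprocess -> LA scan -> selection ->
# grouping -> hypergraph, with a JSON run manifest and reproducible seeds.

#' Build a validated pipeline configuration
#'
#' Collects every hyper-parameter of the workflow. Defaults follow common
#' practice for large-sample expression data: screen constant `c = 0.5`,
#' local fdr target 0.01, minimum fold change 2 (supervised) or 10
#' (unsupervised), minimum cluster size 100 (scaled down automatically,
#' with a warning, when the data has few genes).
#'
#' @param expression Path to a TSV/CSV expression matrix, or a numeric
#'   genes-by-samples matrix with dimnames.
#' @param mode `"supervised"` or `"unsupervised"` gene grouping.
#' @param gmt Path to a GMT gene-set file, or a named list of gene sets
#'   (required for supervised mode).
#' @param c Screen width constant (non-negative).
#' @param fdr_target Local fdr target in (0, 1).
#' @param min_fold_change Hyperedge fold-change threshold; `NULL` picks 2
#'   (supervised) or 10 (unsupervised).
#' @param min_cluster_size Minimum unsupervised cluster size.
#' @param max_zero_fraction Gene zero-fraction filter for file input.
#' @param n_permutations Permutations pooled per scout.
#' @param seed Integer master seed (required for reproducibility).
#' @param out_dir Output directory.
#' @param min_set_size,max_set_size Supervised gene-set size window.
#' @param genes_subset Optional character vector restricting the scan to
#'   these gene identifiers.
#' @param top_variance Optional integer: keep only the most variable
#'   genes, bounding the scan for desk-scale runs.
#' @return A list of class `la_config`.
#' @export
la_config <- function(expression, mode = c("unsupervised", "supervised"),
                      gmt = NULL, c = 0.5, fdr_target = 0.01,
                      min_fold_change = NULL, min_cluster_size = 100L,
                      max_zero_fraction = 0.10, n_permutations = 1L,
                      seed = 1L, out_dir = "lahyper_out",
                      min_set_size = 5L, max_set_size = 500L,
                      genes_subset = NULL, top_variance = NULL) {
  mode <- match.arg(mode)
  if (mode == "supervised" && is.null(gmt)) {
    stop("supervised mode requires a gene-set collection (gmt)")
  }
  stopifnot(c >= 0, fdr_target > 0, fdr_target < 1,
            max_zero_fraction >= 0, max_zero_fraction <= 1,
            n_permutations >= 1L, min_cluster_size >= 2L)
  if (is.null(min_fold_change)) {
    min_fold_change <- if (mode == "supervised") 2 else 10
  }
  stopifnot(min_fold_change >= 0)
  structure(list(expression = expression, mode = mode, gmt = gmt, c = c,
                 fdr_target = fdr_target, min_fold_change = min_fold_change,
                 min_cluster_size = as.integer(min_cluster_size),
                 max_zero_fraction = max_zero_fraction,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), out_dir = out_dir,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 genes_subset = genes_subset, top_variance = top_variance),
            class = "la_config")
}

#' Run the full dynamic-correlation hypergraph pipeline
#'
#' Executes preprocess, Liquid Association scan, permutation-fdr triplet
#' selection, gene grouping and hypergraph construction, and writes
#' `triplets.tsv`, `modules.tsv`, `hyperedges.tsv`, `graph.graphml`,
#' `manifest.json` and `run.log` to the output directory. Identical
#' configuration and seed produce byte-identical outputs.
#'
#' @param config An [la_config()].
#' @return Invisibly, a list with the in-memory stage results:
#'   `matrix` (transformed), `summary`, `mask`, `selection`,
#'   `assignment`, `graph` (thresholded hypergraph), `graph_full`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "la_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- preprocess ------------------------------------------------------
  raw <- stage("preprocess", {
    if (is.character(config$expression)) {
      suppressMessages(load_expression(config$expression,
                                       config$max_zero_fraction))
    } else if (is.matrix(config$expression)) {
      config$expression
    } else stop("expression must be a file path or a numeric matrix")
  })
  if (is.null(rownames(raw))) rownames(raw) <- sprintf("g%04d", seq_len(nrow(raw)))
  if (!is.null(config$genes_subset)) {
    raw <- raw[rownames(raw) %in% config$genes_subset, , drop = FALSE]
  }
  if (!is.null(config$top_variance) && config$top_variance < nrow(raw)) {
    v <- apply(raw, 1L, stats::var)
    keep <- sort(order(-v)[seq_len(config$top_variance)])  # keep input order
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) < 3L || ncol(raw) < 4L) {
    stop("stage 'preprocess' failed: need at least 3 genes and 4 samples")
  }
  note("preprocess: %d genes x %d samples", nrow(raw), ncol(raw))
  tmat <- stage("preprocess", normal_score_transform(raw))
  summary <- stage("preprocess", screen_summary(tmat, config$c))
  mask <- stage("preprocess", eligible_pairs(tmat, summary))
  note("screen: mu=%.4f sigma=%.4f interval=(%.4f, %.4f), %.1f%% of pairs eligible",
       summary$mu, summary$sigma, summary$lower, summary$upper,
       100 * mean(mask[upper.tri(mask)]))

  # -- scan + selection ------------------------------------------------
  selection <- stage("selection", {
    la_select(tmat, mask, fdr_target = config$fdr_target,
              n_permutations = config$n_permutations, seed = config$seed)
  })
  gene_ids <- rownames(tmat)
  note("selection: %d raw per-scout records, %d canonical triplets at fdr %.3g",
       selection$n_scanned, nrow(selection$triplets), config$fdr_target)
  write_triplets_tsv(selection$triplets, gene_ids,
                     file.path(config$out_dir, "triplets.tsv"))
  partial <- nrow(selection$triplets) == 0L

  # -- grouping --------------------------------------------------------
  assignment <- NULL
  if (!partial) {
    assignment <- stage("grouping", {
      if (config$mode == "supervised") {
        coll <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
        assign_supervised(gene_ids, coll, config$min_set_size,
                          config$max_set_size)
      } else {
        A <- build_pair_count_matrix(selection$triplets, nrow(tmat))
        rownames(A) <- colnames(A) <- gene_ids
        D <- pair_profile_distance(A)
        mcs <- config$min_cluster_size
        if (mcs > nrow(D) / 2) {
          mcs <- max(2L, nrow(D) %/% 10L)
          warning(sprintf("min_cluster_size scaled down to %d for %d clusterable genes",
                          mcs, nrow(D)))
          note("grouping: min_cluster_size scaled down to %d", mcs)
        }
        cluster_unsupervised(D, mcs)
      }
    })
    note("grouping (%s): %d modules, %d genes assigned, %d dropped",
         assignment$mode, length(assignment$module_sizes),
         length(assignment$membership), length(assignment$dropped))
    write_modules_tsv(assignment, file.path(config$out_dir, "modules.tsv"))
  }

  # -- hypergraph ------------------------------------------------------
  graph_full <- NULL
  graph <- NULL
  if (!partial) {
    lifted <- stage("hypergraph", {
      lift_triplets(selection$triplets, assignment, gene_ids)
    })
    if (nrow(lifted) == 0L) {
      partial <- TRUE
      note("hypergraph: no triplet survived lifting; outputs incomplete")
    } else {
      note("hypergraph: %d lifted triples (%d gene triplets discarded)",
           nrow(lifted), attr(lifted, "n_discarded"))
      graph_full <- stage("hypergraph", build_hypergraph(lifted, assignment))
      graph <- stage("hypergraph", {
        threshold_edges(graph_full, config$min_fold_change)
      })
      note("hypergraph: %d/%d edges kept at fold change >= %.3g, median degree %s",
           nrow(graph$edges), nrow(graph_full$edges), config$min_fold_change,
           format(graph$median_degree))
      write_hyperedges_tsv(graph, file.path(config$out_dir, "hyperedges.tsv"))
      if (nrow(graph$edges) > 0L) {
        write_hypergraph_graphml(graph, file.path(config$out_dir, "graph.graphml"))
      }
    }
  }

  # -- manifest --------------------------------------------------------
  cfg_out <- unclass(config)[setdiff(names(config), c("expression", "gmt"))]
  cfg_out$gmt <- if (is.character(config$gmt)) config$gmt else if (!is.null(config$gmt)) "<collection>" else NULL
  manifest <- list(
    config = cfg_out,
    expression = if (is.character(config$expression)) config$expression else "<matrix>",
    n_genes = nrow(tmat), n_samples = ncol(tmat),
    screen = list(mu = summary$mu, sigma = summary$sigma, c = summary$c,
                  lower = summary$lower, upper = summary$upper),
    n_raw_records = selection$n_scanned,
    n_triplets = nrow(selection$triplets),
    n_modules = if (is.null(assignment)) 0L else length(assignment$module_sizes),
    n_hyperedges = if (is.null(graph)) 0L else nrow(graph$edges),
    median_degree = if (is.null(graph)) NA else graph$median_degree,
    partial = partial)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(matrix = tmat, summary = summary, mask = mask,
                 selection = selection, assignment = assignment,
                 graph = graph, graph_full = graph_full,
                 out_dir = config$out_dir))
}
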