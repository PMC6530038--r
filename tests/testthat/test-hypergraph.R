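# A tiny assignment used across these tests.
toy_assignment <- function(membership, sizes = NULL) {
  if (is.null(sizes)) {
    labs <- unlist(membership, use.names = FALSE)
    sizes <- table(labs)
    sizes <- stats::setNames(as.integer(sizes), names(sizes))
  }
  structure(list(mode = "supervised", membership = membership,
                 dropped = character(0), module_sizes = sizes),
            class = "module_assignment")
}

# All multisets of size 3 over a label set.
all_multisets <- function(labels) {
  g <- expand.grid(a = labels, b = labels, c = labels,
                   stringsAsFactors = FALSE)
  keys <- apply(g, 1, function(v) paste(sort(v), collapse = "\r"))
  unique(lapply(strsplit(unique(keys), "\r"), identity))
}

test_that("edge type counts distinct labels", {
  expect_equal(classify_edge_type(c("a", "a", "a")), 1L)
  expect_equal(classify_edge_type(c("a", "a", "b")), 2L)
  expect_equal(classify_edge_type(c("a", "b", "c")), 3L)
  expect_error(classify_edge_type(c("a", "b")), "exactly 3")
})

test_that("placement probabilities normalize and match direct enumeration", {
  sizes <- c(a = 3L, b = 4L, c = 5L, d = 6L)
  for (model in c("without", "with")) {
    tot <- sum(vapply(all_multisets(names(sizes)), function(ms) {
      expected_count(unlist(ms), sizes, total_lifted = 1, model = model)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # two modules of 3 genes each, 20 triples: {a,a,b} expects 9
  sz <- c(a = 3L, b = 3L)
  expect_equal(expected_count(c("a", "a", "b"), sz, 20), 9, tolerance = 1e-12)
  # cross-check by enumerating all 20 triples of 6 labelled genes
  labs <- rep(c("a", "b"), each = 3)
  combos <- combn(6, 3)
  n_aab <- sum(apply(combos, 2, function(v) {
    identical(sort(labs[v]), c("a", "a", "b"))
  }))
  expect_equal(n_aab, 9)
  expect_error(expected_count(c("a", "a", "x"), sz, 10), "unknown")
})

test_that("lifting expands multi-membership and drops unassigned genes", {
  memb <- list(g1 = "a", g2 = "a", g3 = "b", g4 = c("a", "b"),
               g5 = "c", g6 = "d")
  asg <- toy_assignment(memb)
  ids <- paste0("g", 1:7)  # g7 has no module
  tri <- data.frame(i = c(1L, 4L, 1L), j = c(2L, 5L, 2L), k = c(3L, 6L, 7L))
  lifted <- lift_triplets(tri, asg, ids)
  expect_equal(attr(lifted, "n_discarded"), 1L)  # the g7 triplet
  expect_equal(nrow(lifted), 1L + 2L)
  expect_equal(unname(lifted[1, ]), c("a", "a", "b"))
  # {a,b} x {c} x {d} -> {a,c,d}, {b,c,d}
  expect_setequal(apply(lifted[2:3, ], 1, paste, collapse = ""),
                  c("acd", "bcd"))

  set.seed(33)
  memb_r <- lapply(stats::setNames(seq_len(9), paste0("g", 1:9)), function(i) {
    sample(letters[1:4], sample(1:2, 1))
  })
  tri_r <- data.frame(t(replicate(30, sort(sample.int(9, 3)))))
  names(tri_r) <- c("i", "j", "k")
  asg_r <- toy_assignment(memb_r)
  got <- lift_triplets(tri_r, asg_r, paste0("g", 1:9))
  want <- brute_lift(tri_r, memb_r, paste0("g", 1:9))
  expect_equal(sort(apply(got, 1, paste, collapse = "|")),
               sort(apply(want, 1, paste, collapse = "|")))
})

test_that("hypergraph aggregation conserves lifted triples", {
  asg <- toy_assignment(list(g1 = "a", g2 = "b", g3 = "c"),
                        sizes = c(a = 4L, b = 3L, c = 5L))
  lifted <- rbind(c("a", "b", "c"), c("a", "b", "c"), c("a", "a", "b"))
  g <- build_hypergraph(lifted, asg)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$count), c(1L, 2L))
  expect_equal(sum(g$edges$count), g$total_lifted)
  expect_equal(g$edges$fold_change, g$edges$count / g$edges$expected)
  abc <- g$edges[g$edges$m3 == "c", ]
  expect_equal(abc$edge_type, 3L)

  set.seed(44)
  sizes <- c(a = 5L, b = 5L, c = 5L, d = 5L)
  lifted_r <- t(replicate(200, sort(sample(names(sizes), 3, replace = TRUE))))
  gr <- build_hypergraph(lifted_r, toy_assignment(list(), sizes))
  # sort-and-group oracle
  keys <- apply(lifted_r, 1, paste, collapse = "|")
  want <- sort(table(keys))
  got <- sort(stats::setNames(gr$edges$count,
                              paste(gr$edges$m1, gr$edges$m2, gr$edges$m3, sep = "|")))
  expect_equal(as.integer(got), as.integer(want))
  expect_identical(names(got), names(want))
  expect_equal(sum(gr$edges$count), 200L)
  expect_error(build_hypergraph(lifted_r[0, ], asg), "no lifted")
})

test_that("random uniform placement gives mean fold change near 1", {
  set.seed(55)
  genes <- sprintf("g%03d", 1:100)
  memb <- stats::setNames(as.list(rep(LETTERS[1:4], each = 25)), genes)
  asg <- toy_assignment(memb)
  tri <- t(replicate(10000, sort(sample.int(100, 3))))
  lifted <- lift_triplets(data.frame(i = tri[, 1], j = tri[, 2], k = tri[, 3]),
                          asg, genes)
  g <- build_hypergraph(lifted, asg)
  expect_equal(mean(g$edges$fold_change), 1, tolerance = 0.05)
})

test_that("thresholding keeps strong edges and reports degrees", {
  asg <- toy_assignment(list(), sizes = c(A = 10L, B = 10L, C = 10L, D = 10L))
  set.seed(66)
  lifted <- t(replicate(300, sort(sample(LETTERS[1:4], 3, replace = TRUE))))
  g <- build_hypergraph(lifted, asg)
  # zero threshold is the identity on edges
  g0 <- threshold_edges(g, 0)
  expect_equal(nrow(g0$edges), nrow(g$edges))
  thr <- stats::median(g$edges$fold_change)
  gt <- threshold_edges(g, thr)
  expect_true(all(gt$edges$fold_change >= thr))
  # every retained vertex touches an edge; degree counted once per edge
  for (v in gt$vertices$module) {
    inc <- gt$edges$m1 == v | gt$edges$m2 == v | gt$edges$m3 == v
    expect_equal(gt$vertices$degree[gt$vertices$module == v], sum(inc))
  }
  expect_equal(gt$median_degree, stats::median(gt$vertices$degree))

  # suggested threshold agrees with an exhaustive scan
  target <- 3
  cands <- sort(unique(c(0, g$edges$fold_change)))
  oracle <- NA_real_
  for (t in cands) {
    gg <- threshold_edges(g, t)
    if (nrow(gg$vertices) && gg$median_degree <= target) { oracle <- t; break }
  }
  expect_equal(suggest_threshold(g, target), oracle)
})

test_that("ego and top-k extraction match brute-force filters", {
  asg <- toy_assignment(list(), sizes = stats::setNames(rep(5L, 6), LETTERS[1:6]))
  set.seed(77)
  lifted <- t(replicate(150, sort(sample(LETTERS[1:6], 3, replace = TRUE))))
  g <- threshold_edges(build_hypergraph(lifted, asg), 0)

  ego <- ego_subhypergraph(g, "C")
  inc <- g$edges$m1 == "C" | g$edges$m2 == "C" | g$edges$m3 == "C"
  expect_equal(ego$edges, g$edges[inc, ], ignore_attr = TRUE)
  expect_setequal(ego$vertices$module,
                  unique(c("C", unlist(g$edges[inc, c("m1", "m2", "m3")]))))
  expect_error(ego_subhypergraph(g, "Z"), "unknown vertex")

  for (k in c(1, 3, 10)) {
    sub <- top_k_subhypergraph(g, k)
    deg <- vertex_degrees(g)
    top <- names(sort(deg, decreasing = TRUE))  # stable within ties?
    top <- names(deg)[order(-deg, names(deg))][seq_len(min(k, length(deg)))]
    expect_setequal(sub$vertices$module, top)
    keep <- apply(g$edges[, c("m1", "m2", "m3")], 1,
                  function(v) all(v %in% top))
    expect_equal(nrow(sub$edges), sum(keep))
  }
})

test_that("gene-level subgraph counts agree with the parent hyperedge", {
  memb <- list(g1 = c("a", "b"), g2 = "a", g3 = "c", g4 = "a", g5 = "b")
  asg <- toy_assignment(memb)
  ids <- paste0("g", 1:5)
  tri <- data.frame(i = c(1L, 2L, 1L), j = c(2L, 4L, 4L), k = c(3L, 3L, 5L))
  lifted <- lift_triplets(tri, asg, ids)
  g <- build_hypergraph(lifted, asg)
  aac <- g$edges[g$edges$m1 == "a" & g$edges$m2 == "a" & g$edges$m3 == "c", ]
  sub <- gene_level_subhypergraph(tri, asg, ids, c("a", "a", "c"))
  expect_equal(sum(sub$edges$count), aac$count)
  expect_true(all(sub$vertices$size >= 1))
  expect_error(gene_level_subhypergraph(tri, asg, ids, c("x", "y", "z")),
               "not an edge")
})

test_that("clique expansion emits the distinct binary edges per type", {
  asg <- toy_assignment(list(), sizes = c(a = 3L, b = 3L, c = 3L))
  lifted <- rbind(c("a", "a", "a"), c("a", "a", "b"), c("a", "b", "c"))
  g <- build_hypergraph(lifted, asg)
  ce <- clique_expansion(g)
  n_by_type <- table(g$edges$edge_type)
  # type 1 -> 1 self-loop, type 2 -> 2 edges, type 3 -> 3 edges
  expect_equal(nrow(ce), 1L + 2L + 3L)
  expect_true(any(ce$from == ce$to))  # self-loop present
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_hypergraph_graphml(g, tf)
  expect_true(file.exists(tf) && file.size(tf) > 0)
  gg <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(gg), 3)
  expect_equal(igraph::ecount(gg), 6)
})
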