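test_that("GMT files round-trip and are validated", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tanother\tg2\tg4",
               "setC\t\tg5\tg6\tg7\tg8"), tf)
  sets <- read_gmt(tf)
  expect_named(sets, c("setA", "setB", "setC"))
  expect_identical(sets$setB, c("g2", "g4"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tonlydesc"), bad)
  expect_error(read_gmt(bad), "malformed")
  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\td\tg1\tg2", "setA\td\tg3\tg4"), dup)
  expect_error(read_gmt(dup), "duplicate")
})

test_that("supervised assignment filters sets and preserves multi-membership", {
  genes <- paste0("g", 1:10)
  coll <- list(small = c("g1", "g2"),                    # below min size
               mid = c("g1", "g2", "g3", "g4", "g9"),
               other = c("g3", "g5", "g6", "g7", "g8"),
               alien = paste0("x", 1:8))                 # no overlap
  a <- assign_supervised(genes, coll, min_set_size = 3, max_set_size = 10)
  expect_identical(sort(names(a$module_sizes)), c("mid", "other"))
  expect_identical(sort(a$membership$g3), c("mid", "other"))  # two modules
  expect_identical(a$membership$g9, "mid")
  expect_identical(a$dropped, "g10")
  expect_error(assign_supervised(genes, list()), "empty")
  expect_error(assign_supervised(genes, coll, min_set_size = 6, max_set_size = 7),
               "no gene set")
})

test_that("pair count matrix equals an explicit tally and conserves mass", {
  one <- data.frame(i = 1L, j = 2L, k = 3L)
  A1 <- build_pair_count_matrix(one, 4)
  expect_equal(sum(A1), 6)
  expect_equal(A1[1, 2], 1); expect_equal(A1[3, 1], 1); expect_equal(A1[2, 3], 1)
  expect_true(all(diag(A1) == 0))

  expect_equal(build_pair_count_matrix(one[0, ], 5), matrix(0L, 5, 5))
  expect_error(build_pair_count_matrix(data.frame(i = 1, j = 2, k = 9), 5),
               "out of range")

  set.seed(22)
  tri <- data.frame(t(replicate(50, sort(sample.int(12, 3)))))
  names(tri) <- c("i", "j", "k")
  A <- build_pair_count_matrix(tri, 12)
  expect_equal(A, brute_pair_tally(tri, 12))
  expect_true(isSymmetric(A))
  expect_equal(sum(A), 6 * nrow(tri))
})

test_that("profile distance is 1 minus row correlation, dropping idle genes", {
  A <- matrix(0L, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  A[1, 2] <- A[2, 1] <- 4L; A[1, 3] <- A[3, 1] <- 2L
  A[2, 3] <- A[3, 2] <- 1L; A[3, 4] <- A[4, 3] <- 5L
  # gene 5 appears in nothing
  D <- pair_profile_distance(A)
  expect_identical(attr(D, "excluded"), "g5")
  expect_equal(dim(D), c(4L, 4L))
  C <- cor(t(A[1:4, ]))
  expect_equal(unname(D), unname(1 - C), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(diag(D)) < 1e-12))
  # identical profiles at distance 0, anti-varying at 2
  B <- rbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(3, 2, 1, 0), c(1, 1, 0, 1))
  DB <- 1 - cor(t(B))
  expect_equal(DB[1, 2], 0, tolerance = 1e-12)
  expect_equal(DB[1, 3], 2, tolerance = 1e-12)
})

make_block_distance <- function(sizes, seed = 1, within = 0.05, between = 0.95) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(between, n, n) + matrix(runif(n * n, -0.03, 0.03), n, n)
  same <- outer(lab, lab, "==")
  D[same] <- within + runif(sum(same), -0.03, 0.03)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- sprintf("g%03d", seq_len(n))
  list(D = D, labels = lab)
}

test_that("adaptive tree cut recovers planted blocks exactly", {
  bl <- make_block_distance(c(30, 30), seed = 42)
  a <- cluster_unsupervised(bl$D, min_cluster_size = 20)
  expect_length(a$module_sizes, 2)
  expect_equal(sort(unname(a$module_sizes)), c(30L, 30L))
  got <- unlist(a$membership)[rownames(bl$D)]
  expect_equal(length(unique(got[bl$labels == 1])), 1L)
  expect_equal(length(unique(got[bl$labels == 2])), 1L)
  expect_error(cluster_unsupervised(bl$D, min_cluster_size = 100), "exceeds")
  expect_error(cluster_unsupervised(bl$D, min_cluster_size = 1), "at least 2")
})

test_that("clustering is deterministic and equivariant to gene order", {
  bl <- make_block_distance(c(25, 20, 22), seed = 7)
  a1 <- cluster_unsupervised(bl$D, 15)
  a2 <- cluster_unsupervised(bl$D, 15)
  expect_identical(a1$membership, a2$membership)
  set.seed(99)
  perm <- sample(nrow(bl$D))
  Dp <- bl$D[perm, perm]
  ap <- cluster_unsupervised(Dp, 15)
  # same partition as sets of gene ids
  part <- function(a) {
    sp <- split(names(a$membership), unlist(a$membership))
    unname(lapply(sp, sort))[order(vapply(lapply(sp, sort), `[[`, "", 1))]
  }
  expect_equal(part(a1), part(ap))
})
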