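# Independent brute-force oracles used across the suite. These deliberately
# use naive loops so they share no code with the implementation.

# All eligible triplets and their scores by a triple loop.
brute_triplets <- function(x, mask) {
  n <- nrow(x)
  out <- list()
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    if (mask[i, j] && mask[i, k] && mask[j, k]) {
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j, k = k, lam = mean(x[i, ] * x[j, ] * x[k, ]))
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      lam = numeric(0)))
  }
  do.call(rbind, out)
}

# Pair co-involvement tally by explicit increments.
brute_pair_tally <- function(triplets, n) {
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(triplets))) {
    v <- as.integer(triplets[r, c("i", "j", "k")])
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- v[p[1]]; b <- v[p[2]]
      A[a, b] <- A[a, b] + 1L
      A[b, a] <- A[b, a] + 1L
    }
  }
  A
}

# Cartesian-product lifting by explicit nested loops.
brute_lift <- function(triplets, membership, gene_ids) {
  rows <- list()
  for (r in seq_len(nrow(triplets))) {
    m1 <- membership[[gene_ids[triplets$i[r]]]]
    m2 <- membership[[gene_ids[triplets$j[r]]]]
    m3 <- membership[[gene_ids[triplets$k[r]]]]
    if (is.null(m1) || is.null(m2) || is.null(m3)) next
    for (a in m1) for (b in m2) for (c in m3) {
      rows[[length(rows) + 1L]] <- sort(c(a, b, c))
    }
  }
  if (!length(rows)) return(matrix(character(0), ncol = 3))
  do.call(rbind, rows)
}

# Random symmetric eligibility mask with FALSE diagonal.
random_mask <- function(n, p = 0.6) {
  m <- matrix(FALSE, n, n)
  up <- which(upper.tri(m))
  m[up] <- stats::runif(length(up)) < p
  m <- m | t(m)
  diag(m) <- FALSE
  m
}

all_true_mask <- function(n) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

# Sorted canonical key strings for set comparison of triplet tables.
triplet_keys <- function(df) sort(paste(df$i, df$j, df$k))
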