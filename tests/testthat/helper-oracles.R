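# Brute-force graph-metric oracles, kept deliberately naive and independent
# of the package implementation (explicit loops, no shared helpers).

oracle_strength <- function(W) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i) s[i] <- s[i] + W[i, j]
    }
  }
  s
}

oracle_clustering_binary <- function(A) {
  n <- nrow(A)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    tri <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h &&
            A[i, j] == 1 && A[i, h] == 1 && A[j, h] == 1) {
          tri <- tri + 1
        }
      }
    }
    tri <- tri / 2
    c_i[i] <- if (k >= 2) 2 * tri / (k * (k - 1)) else 0
  }
  c_i
}

oracle_clustering_onnela <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  wh <- if (mx > 0) (W / mx)^(1 / 3) else W * 0
  A <- (W > 0) * 1
  k <- rowSums(A)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i) acc <- acc + wh[i, j] * wh[j, h] * wh[h, i]
      }
    }
    c_i[i] <- if (k[i] >= 2) acc / (k[i] * (k[i] - 1)) else 0
  }
  c_i
}

# all-pairs shortest paths by Floyd-Warshall on a length matrix (Inf = no
# edge), then average inverse distance
oracle_efficiency <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  diag(D) <- Inf
  sum(1 / D[is.finite(D)]) / (n * (n - 1))
}

# random symmetric weighted graph (positive weights on a random support)
random_weighted_graph <- function(n, p_edge = 0.4) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        w <- runif(1, 0.05, 1)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

# enumerate every labelled undirected graph on n nodes (n small!)
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}
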