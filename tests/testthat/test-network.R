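test_that("rank correlation matches an independent mid-rank computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(5, 6, 7, 8, 7)          # note the tied 7s: mid-ranks apply
  # independent oracle: explicit mid-ranks, then Pearson
  rx <- rank(x)
  ry <- rank(y)                  # 1 2 3.5 5 3.5
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(oracle, 0.8207827, tolerance = 1e-6)
  expect_equal(oracle, cor(x, y, method = "spearman"))

  m <- rbind(c(x, x), c(y, y))   # >= 10 frames required
  sp <- spearman_matrix(m)
  expect_equal(sp$rho[1, 2], cor(c(x, x), c(y, y), method = "spearman"))
  expect_equal(unname(diag(sp$rho)), c(1, 1))
})

test_that("rho agrees exactly with the reference rank correlation on short inputs", {
  set.seed(8)
  for (rep in 1:20) {
    m <- matrix(sample(1:4, 4 * 10, replace = TRUE), nrow = 4)  # many ties
    sp <- spearman_matrix(m)
    ref <- cor(t(m), method = "spearman")
    expect_equal(unname(sp$rho), unname(ref), tolerance = 1e-12)
  }
})

test_that("rho is invariant under monotone transforms and matrices are symmetric", {
  set.seed(2)
  m <- matrix(rnorm(5 * 60), nrow = 5)
  sp1 <- spearman_matrix(m)
  m2 <- m
  m2[1, ] <- exp(m2[1, ])
  sp2 <- spearman_matrix(m2)
  expect_equal(sp1$rho, sp2$rho)
  expect_equal(sp1$rho, t(sp1$rho))
  expect_equal(sp1$p, t(sp1$p))
  expect_true(all(sp1$p >= 0 & sp1$p <= 1))
})

test_that("asymptotic p-values follow the t transform of rho", {
  set.seed(4)
  m <- matrix(rnorm(3 * 40), nrow = 3)
  sp <- spearman_matrix(m)
  n <- ncol(m)
  r <- sp$rho[1, 2]
  p_ref <- 2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2,
                  lower.tail = FALSE)
  expect_equal(sp$p[1, 2], p_ref)
})

test_that("permutation p-values are seed-reproducible and broadly calibrated", {
  set.seed(5)
  m <- matrix(rnorm(4 * 100), nrow = 4)
  sp1 <- spearman_matrix(m, p_method = "permutation", n_perm = 200, seed = 9)
  sp2 <- spearman_matrix(m, p_method = "permutation", n_perm = 200, seed = 9)
  expect_identical(sp1$p, sp2$p)
  # independent white traces: permutation p should not be systematically tiny
  expect_gt(median(sp1$p[upper.tri(sp1$p)]), 0.1)
})

test_that("constant traces yield non-significant undefined correlations", {
  m <- rbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(sp <- spearman_matrix(m), "constant")
  expect_true(is.na(sp$rho[1, 2]))
  expect_equal(sp$p[1, 2], 1)
  net <- gate_edges(sp)
  expect_equal(sum(net$A[2, ]), 0)
})

test_that("edge gating follows the significance threshold and mode", {
  rho <- matrix(c(1, 0.6, -0.7,
                  0.6, 1, 0.2,
                  -0.7, 0.2, 1), 3, 3)
  p <- matrix(c(0, 0.01, 0.01,
                0.01, 0, 0.5,
                0.01, 0.5, 0), 3, 3)
  sp <- list(rho = rho, p = p, n_frames = 100)

  net <- gate_edges(sp, alpha = 0.05, mode = "weighted_positive")
  expect_equal(net$A[1, 2], 1)
  expect_equal(net$A[2, 1], 1)
  expect_equal(net$W[1, 2], 0.6)
  expect_equal(net$A[1, 3], 0)            # significant but negative
  expect_equal(net$A[2, 3], 0)            # p above alpha

  signed <- gate_edges(sp, mode = "weighted_signed")
  expect_equal(signed$W[1, 3], -0.7)
  binary <- gate_edges(sp, mode = "binary")
  expect_equal(binary$W[1, 3], 1)

  allns <- gate_edges(list(rho = rho, p = matrix(0.5, 3, 3), n_frames = 100))
  expect_true(all(allns$A == 0))
})

test_that("Benjamini-Hochberg gating never adds edges", {
  set.seed(10)
  m <- matrix(rnorm(10 * 200), nrow = 10)
  sp <- spearman_matrix(m)
  raw <- gate_edges(sp, p_adjust = "none")
  bh <- gate_edges(sp, p_adjust = "BH")
  expect_lte(sum(bh$A), sum(raw$A))
  expect_true(all(bh$A[raw$A == 0] == 0))
})

test_that("gated networks satisfy their structural invariants", {
  cfg <- sim_config(seed = 21, n_neurons = 12, duration_s = 60,
                    condition = "hyperconnected")
  net <- build_network(normalize_traces(simulate_traceset(cfg)))
  expect_equal(net$A, t(net$A))
  expect_equal(net$W, t(net$W))
  expect_true(all(diag(net$A) == 0) && all(diag(net$W) == 0))
  expect_true(all((net$A == 1) == (net$W != 0)))
  expect_true(all(net$p[net$A == 1] < net$alpha))
  expect_true(all(abs(net$W) <= 1))
})

test_that("small networks are excluded strictly below the minimum size", {
  mk <- function(n) {
    m <- matrix(rnorm(n * 50), nrow = n)
    gate_edges(spearman_matrix(m))
  }
  nets <- lapply(c(2, 3, 4, 5), mk)
  expect_message(kept <- exclude_small_networks(nets), "excluded 2")
  expect_equal(vapply(kept, function(x) x$n_neurons, numeric(1)), c(4, 5))
  expect_equal(exclude_small_networks(list()), list())
})

test_that("distance control reports degenerate inputs as non-significant", {
  rho <- matrix(0.5, 3, 3)
  diag(rho) <- 1
  fake <- list(rho = rho,
               centroids = tibble::tibble(x = c(0, 1, 2), y = c(0, 0, 0)))
  expect_warning(dc <- distance_control(fake), "undefined")
  expect_true(is.na(dc$estimate))
  expect_false(dc$significant)
})

test_that("distance control detects planted distance-dependent correlation", {
  set.seed(14)
  n <- 15
  cent <- tibble::tibble(x = runif(n, 0, 300), y = runif(n, 0, 300))
  d <- as.matrix(dist(cbind(cent$x, cent$y)))
  rho <- 1 - d / max(d) + matrix(rnorm(n * n, 0, 0.02), n, n)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dc <- distance_control(list(rho = rho, centroids = cent))
  expect_lt(dc$estimate, -0.5)
  expect_true(dc$significant)
  expect_equal(dc$n_pairs, n * (n - 1) / 2)
})
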