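complete_graph <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

test_that("degree and normalized degree on canonical topologies", {
  deg <- node_degree(complete_graph(5))
  expect_equal(deg$degree, rep(4, 5))
  expect_equal(deg$degree_norm, rep(0.8, 5))

  empty <- node_degree(matrix(0, 4, 4))
  expect_equal(empty$degree, rep(0, 4))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ds <- node_degree(star)
  expect_equal(ds$degree_norm, c(0.75, 0.25, 0.25, 0.25))
  # alternative N-1 normalization
  expect_equal(node_degree(star, "n_minus_1")$degree_norm[1], 1)
})

test_that("strength and the above-mean fraction handle ties and hubs", {
  W <- complete_graph(4) * 0.5
  s <- node_strength(W)
  expect_equal(s$strength, rep(1.5, 4))
  expect_equal(attr(s, "above_mean_fraction"), 0)  # ties at the mean excluded

  hub <- matrix(0, 5, 5)
  hub[1, 2] <- hub[2, 1] <- 0.9
  hub[3, 4] <- hub[4, 3] <- 0.1
  sh <- node_strength(hub)
  expect_equal(attr(sh, "above_mean_fraction"), 2 / 5)

  set.seed(6)
  Wr <- random_weighted_graph(9)
  expect_equal(node_strength(Wr)$strength, oracle_strength(Wr))
})

test_that("clustering coefficient on canonical and random graphs", {
  tri <- complete_graph(3)
  expect_equal(clustering_coefficient(tri, "binary")$clustering, rep(1, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(attr(clustering_coefficient(path, "binary"), "mean_clustering"), 0)

  set.seed(7)
  for (rep in 1:5) {
    A <- (random_weighted_graph(10, 0.5) > 0) * 1
    expect_equal(clustering_coefficient(A, "binary")$clustering,
                 oracle_clustering_binary(A))
    W <- random_weighted_graph(8, 0.5)
    expect_equal(clustering_coefficient(W, "onnela_weighted")$clustering,
                 oracle_clustering_onnela(W), tolerance = 1e-12)
  }
})

test_that("density matches its definition", {
  expect_equal(network_density(complete_graph(6)), 1)
  expect_equal(network_density(matrix(0, 5, 5)), 0)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(network_density(A), 0.5)     # 3 of 6 possible edges
  expect_true(is.na(network_density(matrix(0, 1, 1))))
})

test_that("global efficiency against the Floyd-Warshall oracle", {
  expect_equal(global_efficiency(complete_graph(5), "binary"), 1)
  expect_equal(global_efficiency(matrix(0, 6, 6), "binary"), 0)

  set.seed(9)
  for (rep in 1:5) {
    W <- random_weighted_graph(12, 0.3)
    L <- ifelse(W > 0, 1 / W, Inf)
    diag(L) <- Inf
    expect_equal(global_efficiency(W, "weighted"), oracle_efficiency(L),
                 tolerance = 1e-12)
    A <- (W > 0) * 1
    Lb <- ifelse(A > 0, 1, Inf)
    diag(Lb) <- Inf
    expect_equal(global_efficiency(A, "binary"), oracle_efficiency(Lb),
                 tolerance = 1e-12)
  }
})

test_that("weighted efficiency agrees with igraph's shortest paths", {
  skip_if_not_installed("igraph")
  set.seed(10)
  W <- random_weighted_graph(10, 0.4)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  diag(D) <- Inf
  ref <- sum(1 / D[is.finite(D)]) / (10 * 9)
  expect_equal(global_efficiency(W, "weighted"), ref, tolerance = 1e-12)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(11)
  W <- random_weighted_graph(8, 0.5)
  perm <- sample(8)
  Wp <- W[perm, perm]
  expect_equal(sort(node_degree(W)$degree), sort(node_degree(Wp)$degree))
  expect_equal(sort(node_strength(W)$strength),
               sort(node_strength(Wp)$strength), tolerance = 1e-12)
  expect_equal(network_density(W), network_density(Wp))
  expect_equal(global_efficiency(W), global_efficiency(Wp),
               tolerance = 1e-12)
  expect_equal(sort(clustering_coefficient(W)$clustering),
               sort(clustering_coefficient(Wp)$clustering),
               tolerance = 1e-12)
})

test_that("adding an edge never decreases density, degree, or efficiency", {
  set.seed(12)
  for (rep in 1:10) {
    A <- (random_weighted_graph(7, 0.3) > 0) * 1
    absent <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
    expect_gte(network_density(A2), network_density(A))
    expect_true(all(node_degree(A2)$degree >= node_degree(A)$degree))
    expect_gte(global_efficiency(A2, "binary") + 1e-12,
               global_efficiency(A, "binary"))
  }
})

test_that("network_metrics bundles node and network summaries coherently", {
  cfg <- sim_config(seed = 31, n_neurons = 10, duration_s = 60,
                    condition = "hyperconnected")
  net <- build_network(normalize_traces(simulate_traceset(cfg)))
  nm <- network_metrics(net)
  expect_equal(nrow(nm$nodes), 10)
  expect_equal(nm$network$mean_degree_norm, mean(nm$nodes$degree_norm))
  expect_equal(nm$network$density, network_density(net))
  expect_true(all(nm$nodes$degree_norm >= 0 &
                    nm$nodes$degree_norm <= 9 / 10))
  expect_s3_class(tidy(nm), "tbl_df")
  expect_equal(nrow(glance(nm)), 1)
})

test_that("higher ensemble participation raises mean normalized degree", {
  mean_deg <- function(p) {
    vals <- vapply(1:3, function(s) {
      cfg <- sim_config(
        seed = 400 + s, n_neurons = 15, duration_s = 100,
        condition = "hyperconnected",
        ensembles = list(ensemble(1:8, 0.5, p), ensemble(9:15, 0.5, p))
      )
      net <- build_network(normalize_traces(simulate_traceset(cfg)))
      attr(node_degree(net), "mean_degree_norm")
    }, numeric(1))
    mean(vals)
  }
  grid <- c(0.2, 0.5, 0.8)
  vals <- vapply(grid, mean_deg, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("condition comparison recovers direction, null, and power", {
  set.seed(13)
  x <- rnorm(30)
  same <- compare_conditions(tibble::tibble(degree_norm = x),
                             tibble::tibble(degree_norm = x))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$diff, 0)

  # empirical power vs the closed-form noncentral-t power of the t-test
  n <- 10
  delta <- 1.5
  crit <- qt(0.975, 2 * n - 2)
  ncp <- delta / sqrt(2 / n)
  power_theory <- 1 - pt(crit, 2 * n - 2, ncp) + pt(-crit, 2 * n - 2, ncp)
  rej <- vapply(1:300, function(i) {
    a <- rnorm(n)
    b <- rnorm(n, delta)
    t.test(a, b, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  margin <- 2.576 * sqrt(power_theory * (1 - power_theory) / 300)
  expect_lt(abs(mean(rej) - power_theory), margin + 0.01)
})
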