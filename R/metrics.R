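# Accept a correlation_network or a plain adjacency/weight matrix pair.
as_AW <- function(net) {
  if (inherits(net, "correlation_network")) {
    list(A = net$A, W = net$W, n = net$n_neurons)
  } else if (is.matrix(net)) {
    A <- (net != 0) * 1
    diag(A) <- 0
    W <- net
    diag(W) <- 0
    list(A = A, W = W, n = nrow(net))
  } else {
    abort("expected a correlation_network or a square matrix")
  }
}

#' Node degree and normalized node degree
#'
#' The degree of a node is its number of significant connections,
#' \eqn{k_i = \sum_j A_{ij}}. The normalized degree divides by the total
#' number of nodes N in the network (not N - 1), so it represents the
#' average number of connections per neuron and is bounded by
#' \eqn{(N-1)/N}; divide-by-`N - 1` normalization is available via
#' `normalization = "n_minus_1"`.
#'
#' @param net A `correlation_network` or adjacency matrix.
#' @param normalization `"n"` (default) or `"n_minus_1"`.
#' @return A tibble with columns `node`, `degree`, `degree_norm`; the
#'   network mean normalized degree is attached as attribute
#'   `mean_degree_norm`.
#' @export
node_degree <- function(net, normalization = c("n", "n_minus_1")) {
  normalization <- match.arg(normalization)
  g <- as_AW(net)
  if (g$n == 0) abort("empty network: no nodes")
  k <- rowSums(g$A)
  denom <- if (normalization == "n") g$n else g$n - 1
  out <- tibble(node = seq_len(g$n), degree = k, degree_norm = k / denom)
  attr(out, "mean_degree_norm") <- mean(out$degree_norm)
  out
}

#' Node strength and above-mean fraction
#'
#' The strength of a node is the sum of its incident edge weights,
#' \eqn{s_i = \sum_j W_{ij}}. The above-mean fraction — the proportion of
#' nodes whose strength strictly exceeds the network mean strength —
#' summarises how strength concentrates on hubs.
#'
#' @param net A `correlation_network` or weight matrix.
#' @return A tibble with columns `node`, `strength`; attributes
#'   `above_mean_fraction` and `mean_strength`.
#' @export
node_strength <- function(net) {
  g <- as_AW(net)
  s <- rowSums(g$W)
  out <- tibble(node = seq_len(g$n), strength = s)
  attr(out, "mean_strength") <- mean(s)
  attr(out, "above_mean_fraction") <- mean(s > mean(s))
  out
}

#' Clustering coefficient (binary or Onnela weighted)
#'
#' Quantifies the proportion of triangular connections around each node.
#' For binary graphs \eqn{c_i = 2 t_i / (k_i (k_i - 1))} with \eqn{t_i}
#' the number of triangles through node i; nodes with fewer than two
#' neighbours have \eqn{c_i = 0}. The weighted variant is Onnela's
#' geometric-mean form,
#' \eqn{c_i = \sum_{jk} (\hat w_{ij}\hat w_{jk}\hat w_{ik})^{1/3} / (k_i(k_i-1))},
#' with weights rescaled to \[0, 1\] by the network maximum — the standard
#' weighted definition in the brain-connectivity literature.
#'
#' @param net A `correlation_network` or matrix.
#' @param variant `"onnela_weighted"` (default) or `"binary"`.
#' @return A tibble with columns `node`, `clustering`; attribute
#'   `mean_clustering`.
#' @export
clustering_coefficient <- function(net, variant = c("onnela_weighted", "binary")) {
  variant <- match.arg(variant)
  g <- as_AW(net)
  A <- g$A
  k <- rowSums(A)
  if (variant == "binary") {
    t_i <- diag(A %*% A %*% A) / 2
    c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  } else {
    mx <- max(abs(g$W))
    w_hat <- if (mx > 0) (abs(g$W) / mx)^(1 / 3) else g$W * 0
    c_i <- diag(w_hat %*% w_hat %*% w_hat) / (k * (k - 1))
    c_i[k < 2] <- 0
  }
  out <- tibble(node = seq_len(g$n), clustering = c_i)
  attr(out, "mean_clustering") <- mean(c_i)
  out
}

#' Network density
#'
#' Fraction of existing connections out of all possible connections,
#' \eqn{D = \sum_{i<j} A_{ij} / (N(N-1)/2)}. Undefined (NA) for networks
#' with fewer than two nodes.
#'
#' @param net A `correlation_network` or adjacency matrix.
#' @return A single number in \[0, 1\], or `NA` when undefined.
#' @export
network_density <- function(net) {
  g <- as_AW(net)
  if (g$n < 2) return(NA_real_)
  sum(g$A) / (g$n * (g$n - 1))
}

# Dijkstra single-source shortest path lengths on a length matrix
# (Inf = no edge). O(N^2) per source; networks here are small.
dijkstra_lengths <- function(L, src) {
  n <- nrow(L)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- rep(FALSE, n)
  for (step in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (is.na(u) || is.infinite(dist[u])) break
    done[u] <- TRUE
    nb <- which(is.finite(L[u, ]) & !done)
    if (length(nb)) {
      cand <- dist[u] + L[u, nb]
      better <- cand < dist[nb]
      dist[nb[better]] <- cand[better]
    }
  }
  dist
}

#' Global efficiency
#'
#' The average inverse shortest-path length over all ordered node pairs,
#' \eqn{E = \frac{1}{N(N-1)} \sum_{i \neq j} 1/d_{ij}}; disconnected pairs
#' (\eqn{d_{ij} = \infty}) contribute 0. In the weighted variant the edge
#' length is the inverse weight, \eqn{L_{ij} = 1/W_{ij}}, and shortest
#' paths are computed by Dijkstra's algorithm.
#'
#' @param net A `correlation_network` or matrix.
#' @param variant `"weighted"` (default) or `"binary"`.
#' @return A single nonnegative number (at most 1 for binary graphs).
#' @export
global_efficiency <- function(net, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  g <- as_AW(net)
  n <- g$n
  if (n < 2) return(NA_real_)
  L <- if (variant == "binary") {
    ifelse(g$A > 0, 1, Inf)
  } else {
    ifelse(g$W > 0, 1 / g$W, Inf)
  }
  diag(L) <- Inf
  inv_sum <- 0
  for (s in seq_len(n)) {
    d <- dijkstra_lengths(L, s)
    d[s] <- Inf
    inv_sum <- inv_sum + sum(1 / d[is.finite(d)])
  }
  inv_sum / (n * (n - 1))
}

#' All graph statistics of a gated network
#'
#' Computes the full per-node and per-network statistic set: degree and
#' normalized degree, strength, clustering coefficient, and the network
#' summaries (mean normalized degree, mean clustering, density, global
#' efficiency, above-mean strength fraction).
#'
#' @param net A `correlation_network`.
#' @param degree_normalization `"n"` (default) or `"n_minus_1"`.
#' @param clustering_variant `"onnela_weighted"` (default) or `"binary"`.
#' @param efficiency_variant `"weighted"` (default) or `"binary"`.
#' @return An object of class `network_metrics` with `$nodes` (tibble, one
#'   row per node) and `$network` (one-row summary tibble). `tidy()` returns
#'   the node table, `glance()` the summary.
#' @export
network_metrics <- function(net, degree_normalization = c("n", "n_minus_1"),
                            clustering_variant = c("onnela_weighted", "binary"),
                            efficiency_variant = c("weighted", "binary")) {
  stopifnot(inherits(net, "correlation_network"))
  degree_normalization <- match.arg(degree_normalization)
  clustering_variant <- match.arg(clustering_variant)
  efficiency_variant <- match.arg(efficiency_variant)
  deg <- node_degree(net, degree_normalization)
  str <- node_strength(net)
  clu <- clustering_coefficient(net, clustering_variant)
  nodes <- dplyr::left_join(dplyr::left_join(deg, str, by = "node"),
                            clu, by = "node")
  nodes$condition <- net$condition
  nodes$region_label <- net$region_label
  network <- tibble(
    n_nodes = net$n_neurons,
    n_edges = sum(net$A) / 2,
    mean_degree_norm = attr(deg, "mean_degree_norm"),
    mean_strength = attr(str, "mean_strength"),
    strength_above_mean_fraction = attr(str, "above_mean_fraction"),
    mean_clustering = attr(clu, "mean_clustering"),
    density = network_density(net),
    global_efficiency = global_efficiency(net, efficiency_variant),
    condition = net$condition,
    region_label = net$region_label
  )
  structure(list(nodes = nodes, network = network), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("<network_metrics>\n")
  print(x$network)
  invisible(x)
}

#' @method tidy network_metrics
#' @export
tidy.network_metrics <- function(x, ...) x$nodes

#' @method glance network_metrics
#' @export
glance.network_metrics <- function(x, ...) x$network

#' Compare a node-level metric between two conditions
#'
#' Two-sample comparison of a per-node graph statistic (e.g. normalized
#' degree) between two networks or conditions, using node-level samples as
#' the unit of inference — mirroring common practice in imaging studies
#' (note this treats nodes within a field as independent, a form of
#' pseudo-replication acknowledged in the documentation).
#'
#' @param metrics_a,metrics_b `network_metrics` objects (or node tibbles
#'   with the metric column) for the two groups.
#' @param metric Column to compare (default `"degree_norm"`).
#' @param test `"t_test"` (equal-variance, default), `"welch_t"`.
#' @return A one-row tibble: group means and SEMs, mean difference
#'   (b - a), t statistic, degrees of freedom, two-sided p-value, and the
#'   effect direction.
#' @export
compare_conditions <- function(metrics_a, metrics_b, metric = "degree_norm",
                               test = c("t_test", "welch_t")) {
  test <- match.arg(test)
  get_col <- function(m) {
    d <- if (inherits(m, "network_metrics")) m$nodes else as_tibble(m)
    if (!metric %in% names(d)) abort(sprintf("metric '%s' not found", metric))
    d[[metric]]
  }
  a <- get_col(metrics_a)
  b <- get_col(metrics_b)
  group_stats(a, b, test = test, label = metric)
}
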