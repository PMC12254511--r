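#' Pairwise Spearman correlation matrix with p-values
#'
#' Computes Spearman's rank correlation for every neuron pair: traces are
#' rank-transformed with mid-ranks for ties, then the Pearson correlation of
#' the ranks is taken. Two p-value methods are available:
#'
#' * `"asymptotic"` (default) — the t approximation
#'   \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom,
#'   two-sided (the behaviour of common `corr`-style routines).
#' * `"permutation"` — a circular-shift null: each permutation rotates every
#'   neuron's trace by an independent random offset, preserving each trace's
#'   autocorrelation while destroying alignment; the two-sided p-value is
#'   `(1 + #{|rho*| >= |rho|}) / (n_perm + 1)`.
#'
#' Constant traces have undefined rank correlation; their pairs are returned
#' as `rho = NA`, `p = 1` (never significant) with a warning.
#'
#' @param x A [trace_set()] or a numeric matrix (neurons x frames).
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of circular-shift permutations (default 500).
#' @param seed Seed for the permutation null.
#' @return A list of class `spearman_result`: `rho` and `p` (symmetric
#'   N x N matrices, diagonal 1), `n_frames`, and any trace-set metadata
#'   (centroids, condition, region_label) for downstream steps.
#' @export
spearman_matrix <- function(x, p_method = c("asymptotic", "permutation"),
                            n_perm = 500, seed = 1L) {
  p_method <- match.arg(p_method)
  meta <- list(centroids = NULL, condition = NA_character_,
               region_label = NA_character_)
  if (inherits(x, "trace_set")) {
    meta <- x[c("centroids", "condition", "region_label")]
    x <- x$traces
  }
  x <- as.matrix(x)
  n_neurons <- nrow(x)
  n <- ncol(x)
  stopifnot(n_neurons >= 2, n >= 10)

  rank_rho <- function(m) {
    r <- t(apply(m, 1, rank, ties.method = "average"))
    suppressWarnings(cor(t(r)))      # Pearson on ranks; NA for constant rows
  }
  rho <- rank_rho(x)

  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const)) {
    warn(sprintf(
      "constant trace(s) %s: correlations undefined, recorded as non-significant",
      paste(which(const), collapse = ", ")
    ))
  }

  if (p_method == "asymptotic") {
    r2 <- pmin(rho^2, 1 - 1e-15)
    tt <- abs(rho) * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
    p[rho^2 >= 1] <- 0
  } else {
    obs <- abs(rho)
    count <- matrix(0, n_neurons, n_neurons)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        sh <- sample.int(n, n_neurons, replace = TRUE)
        xs <- x
        for (i in seq_len(n_neurons)) {
          xs[i, ] <- x[i, ((seq_len(n) - 1 + sh[i]) %% n) + 1]
        }
        rb <- abs(rank_rho(xs))
        count <- count + (!is.na(rb) & !is.na(obs) & rb >= obs)
      }
    })
    p <- (1 + count) / (n_perm + 1)
  }

  p[is.na(rho)] <- 1
  diag(p) <- 1
  diag(rho) <- 1
  p <- (p + t(p)) / 2          # enforce exact symmetry
  dimnames(rho) <- dimnames(p) <- list(rownames(x), rownames(x))

  structure(
    list(rho = rho, p = p, n_frames = n, p_method = p_method,
         centroids = meta$centroids, condition = meta$condition,
         region_label = meta$region_label),
    class = "spearman_result"
  )
}

new_correlation_network <- function(rho, p, A, W, alpha, mode, n_frames,
                                    centroids = NULL,
                                    condition = NA_character_,
                                    region_label = NA_character_) {
  n <- nrow(A)
  stopifnot(
    isTRUE(all.equal(A, t(A))), all(diag(A) == 0),
    isTRUE(all.equal(W, t(W), tolerance = 1e-12)), all(diag(W) == 0),
    all(abs(W) <= 1 + 1e-12),
    all((A == 1) == (W != 0)),
    all(p[A == 1] < alpha)
  )
  structure(
    list(rho = rho, p = p, A = A, W = W, alpha = alpha, mode = mode,
         n_frames = n_frames, n_neurons = n, centroids = centroids,
         condition = condition, region_label = region_label),
    class = "correlation_network"
  )
}

#' Gate correlation edges by significance
#'
#' Converts a correlation/p-value matrix pair into a functional connectivity
#' network: an edge is retained when its p-value is below `alpha`
#' (and, in the default `"weighted_positive"` mode, its correlation is
#' positive). The weight matrix `W` carries the Spearman rho on retained
#' edges and 0 elsewhere; the adjacency `A` is its binary support. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg is
#' available via `p_adjust = "BH"`.
#'
#' @param sp A `spearman_result` from [spearman_matrix()] (or a list with
#'   `rho` and `p` matrices and `n_frames`).
#' @param alpha Significance threshold (default 0.05).
#' @param mode `"weighted_positive"` (default; significant positive edges),
#'   `"binary"` (all significant edges, weight 1), or `"weighted_signed"`
#'   (significant edges keep signed rho).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A `correlation_network`; its invariants (symmetry, zero
#'   diagonal, `A == support(W)`, gated p-values below alpha) are asserted
#'   on construction.
#' @export
gate_edges <- function(sp, alpha = 0.05,
                       mode = c("weighted_positive", "binary",
                                "weighted_signed"),
                       p_adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  rho <- sp$rho
  p <- sp$p
  n <- nrow(rho)
  stopifnot(!is.null(p), all(dim(p) == dim(rho)))

  if (p_adjust == "BH") {
    up <- upper.tri(p)
    adj <- p.adjust(p[up], method = "BH")
    p_gate <- p
    p_gate[up] <- adj
    p_gate <- pmin(p_gate, t(p_gate))
    diag(p_gate) <- 1
  } else {
    p_gate <- p
  }

  sig <- p_gate < alpha & !is.na(rho)
  diag(sig) <- FALSE
  keep <- switch(mode,
    weighted_positive = sig & rho > 0,
    binary = sig,
    weighted_signed = sig
  )
  A <- matrix(0, n, n)
  A[keep] <- 1
  W <- matrix(0, n, n)
  W[keep] <- switch(mode,
    weighted_positive = rho[keep],
    binary = 1,
    weighted_signed = rho[keep]
  )
  dimnames(A) <- dimnames(W) <- dimnames(rho)

  new_correlation_network(
    rho, p_gate, A, W, alpha, mode, sp$n_frames,
    centroids = sp$centroids, condition = sp$condition %||% NA_character_,
    region_label = sp$region_label %||% NA_character_
  )
}

#' Build a gated correlation network from traces in one step
#'
#' Convenience chain: [spearman_matrix()] then [gate_edges()].
#'
#' @inheritParams spearman_matrix
#' @inheritParams gate_edges
#' @return A `correlation_network`.
#' @export
build_network <- function(x, alpha = 0.05,
                          mode = c("weighted_positive", "binary",
                                   "weighted_signed"),
                          p_method = c("asymptotic", "permutation"),
                          p_adjust = c("none", "BH"),
                          n_perm = 500, seed = 1L) {
  gate_edges(
    spearman_matrix(x, p_method = p_method, n_perm = n_perm, seed = seed),
    alpha = alpha, mode = match.arg(mode), p_adjust = match.arg(p_adjust)
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d neurons, %d edges (alpha %g, %s mode)\n",
    x$n_neurons, sum(x$A) / 2, x$alpha, x$mode
  ))
  invisible(x)
}

#' Edge list of a gated network
#'
#' @param x A `correlation_network`.
#' @param ... Unused.
#' @return A tibble with one row per retained undirected edge: `from`,
#'   `to`, `rho`, `p`.
#' @method tidy correlation_network
#' @export
tidy.correlation_network <- function(x, ...) {
  up <- which(upper.tri(x$A) & x$A == 1, arr.ind = TRUE)
  tibble(
    from = up[, 1], to = up[, 2],
    rho = x$rho[up], p = x$p[up], weight = x$W[up]
  )
}

#' @method glance correlation_network
#' @export
glance.correlation_network <- function(x, ...) {
  n <- x$n_neurons
  tibble(
    n_neurons = n, n_edges = sum(x$A) / 2,
    density = if (n >= 2) sum(x$A) / (n * (n - 1)) else NA_real_,
    alpha = x$alpha, mode = x$mode, n_frames = x$n_frames,
    condition = x$condition, region_label = x$region_label
  )
}

#' Drop networks below the minimum analyzable size
#'
#' Fields of view yielding very small networks are excluded from group
#' analysis: networks with fewer than `min_neurons` neurons (default 4) are
#' removed, strictly — a network of exactly `min_neurons` is retained.
#'
#' @param nets A list of `correlation_network` objects (a single network is
#'   accepted and wrapped).
#' @param min_neurons Minimum neuron count to retain (default 4).
#' @return The filtered list; a message reports how many were excluded.
#' @export
exclude_small_networks <- function(nets, min_neurons = 4) {
  if (inherits(nets, "correlation_network")) nets <- list(nets)
  sizes <- vapply(nets, function(x) x$n_neurons, numeric(1))
  keep <- sizes >= min_neurons
  if (any(!keep)) {
    inform(sprintf(
      "excluded %d network(s) with fewer than %d neurons (sizes: %s)",
      sum(!keep), min_neurons, paste(sizes[!keep], collapse = ", ")
    ))
  }
  nets[keep]
}

#' Distance-versus-correlation spatial control
#'
#' Tests whether functional correlation merely reflects spatial proximity:
#' for every unordered neuron pair the Euclidean inter-centroid distance is
#' paired with the Spearman correlation of the two traces, and the
#' association between distance and correlation is itself tested by a
#' two-sided Spearman rank correlation. No association (small rho, p above
#' alpha) indicates that network structure is not a spatial artifact.
#'
#' If either pair vector is constant the association is undefined; the
#' result is returned with `NA` statistics and flagged non-significant.
#'
#' @param net A `correlation_network` (or `spearman_result`) carrying
#'   centroids, or any such object plus an explicit `centroids` data frame
#'   with `x`, `y` columns.
#' @param centroids Optional centroid data frame overriding the one stored
#'   in `net`.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return A list of class `distance_control`: `pairs` (tibble of
#'   `distance_um`, `rho`), `estimate` (association rho), `p_value`,
#'   `n_pairs`, `significant`.
#' @export
distance_control <- function(net, centroids = NULL, alpha = 0.05) {
  centroids <- centroids %||% net$centroids
  if (is.null(centroids)) abort("centroids are required for the distance control")
  rho <- net$rho
  n <- nrow(rho)
  stopifnot(nrow(centroids) == n)

  d <- as.matrix(stats::dist(cbind(centroids$x, centroids$y)))
  up <- upper.tri(rho)
  pairs <- tibble(distance_um = d[up], rho = rho[up])
  pairs <- pairs[!is.na(pairs$rho), ]

  if (nrow(pairs) < 3 ||
      max(pairs$rho) == min(pairs$rho) ||
      max(pairs$distance_um) == min(pairs$distance_um)) {
    warn("distance-correlation association undefined (constant vector); reported as non-significant")
    est <- NA_real_
    pv <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(pairs$distance_um, pairs$rho, method = "spearman",
                      exact = FALSE)
    )
    est <- unname(ct$estimate)
    pv <- ct$p.value
  }
  structure(
    list(pairs = pairs, estimate = est, p_value = pv,
         n_pairs = nrow(pairs),
         significant = isTRUE(pv < alpha)),
    class = "distance_control"
  )
}

#' @export
print.distance_control <- function(x, ...) {
  cat(sprintf(
    "<distance_control> rho = %s, p = %s over %d pairs (%s)\n",
    format(x$estimate, digits = 3), format(x$p_value, digits = 3),
    x$n_pairs,
    if (isTRUE(x$significant)) "significant" else "no distance-correlation relationship"
  ))
  invisible(x)
}

#' @method glance distance_control
#' @export
glance.distance_control <- function(x, ...) {
  tibble(estimate = x$estimate, p_value = x$p_value, n_pairs = x$n_pairs,
         significant = x$significant)
}
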