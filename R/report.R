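#' Two-group and one-way group statistics
#'
#' Thin, consistently shaped wrapper around the standard tests used for
#' group comparisons: the equal-variance two-sample t-test (default), the
#' Welch t-test, and one-way ANOVA. Summaries report mean and SEM per group
#' (SEM uses the n−1 sd), matching conventional "mean ± SEM" reporting.
#'
#' @param a Numeric vector (first group), or a list of numeric vectors for
#'   `"anova_oneway"`.
#' @param b Numeric vector (second group); ignored for ANOVA when `a` is a
#'   list.
#' @param test `"t_test"`, `"welch_t"`, or `"anova_oneway"`.
#' @param label Optional label describing the compared quantity.
#' @return A one-row tibble: `label`, `test`, `statistic`, `df`
#'   (`df1`/`df2` for ANOVA), two-sided `p_value`, per-group `mean`/`sem`/
#'   `n` (groups a and b for two-sample tests), and `diff` (b − a).
#' @examples
#' group_stats(c(1, 2, 3), c(4, 5, 6))
#' @export
group_stats <- function(a, b = NULL,
                        test = c("t_test", "welch_t", "anova_oneway"),
                        label = NA_character_) {
  test <- match.arg(test)
  sem <- function(x) sd(x) / sqrt(length(x))

  if (test == "anova_oneway") {
    groups <- if (is.list(a)) a else list(a, b)
    stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
    dat <- data.frame(
      y = unlist(groups, use.names = FALSE),
      g = factor(rep.int(seq_along(groups), lengths(groups)))
    )
    fit <- summary(aov(y ~ g, data = dat))[[1]]
    return(tibble(
      label = label, test = test,
      statistic = fit[["F value"]][1],
      df1 = fit[["Df"]][1], df2 = fit[["Df"]][2],
      p_value = fit[["Pr(>F)"]][1],
      n_groups = length(groups),
      grand_mean = mean(dat$y)
    ))
  }

  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    # both groups constant: no within-group variance for a t statistic;
    # report the degenerate comparison directly
    equal <- mean(a) == mean(b)
    return(tibble(
      label = label, test = test,
      statistic = if (equal) 0 else sign(mean(b) - mean(a)) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a), sem_a = 0, n_a = length(a),
      mean_b = mean(b), sem_b = 0, n_b = length(b),
      diff = mean(b) - mean(a)
    ))
  }
  ht <- t.test(b, a, var.equal = (test == "t_test"))
  tibble(
    label = label, test = test,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a), sem_a = sem(a), n_a = length(a),
    mean_b = mean(b), sem_b = sem(b), n_b = length(b),
    diff = mean(b) - mean(a)
  )
}

#' Run the imaging pipeline end to end on two conditions
#'
#' Orchestrates the full analysis on a pair of synthetic fields (or
#' supplied trace sets): normalization, event detection and binning,
#' Spearman correlation, significance gating, small-network exclusion,
#' graph metrics, the distance-versus-correlation control, and the group
#' comparison of a node-level metric. Every parameter and seed used is
#' echoed into the returned `manifest`, so any numeric output can be
#' reproduced from the manifest alone.
#'
#' @param cfg_a,cfg_b [sim_config()] objects for the two conditions, or
#'   ready-made [trace_set()] objects.
#' @param alpha Edge significance threshold (default 0.05).
#' @param mode Gating mode; see [gate_edges()].
#' @param p_method,p_adjust See [spearman_matrix()] / [gate_edges()].
#' @param min_neurons Minimum network size retained (default 4).
#' @param metric Node-level metric compared between conditions (default
#'   `"degree_norm"`).
#' @param normalize_method Trace normalization method (display pathway;
#'   rank statistics are invariant to it).
#' @param bin_width_s Raster bin width, s (default 100).
#' @param test Group test (default equal-variance `"t_test"`).
#' @return A list of class `synconnect_bundle` with elements `trace_sets`,
#'   `rasters`, `networks`, `metrics`, `distance_controls`, `comparison`
#'   (tibble), and `manifest`.
#' @export
run_pipeline <- function(cfg_a, cfg_b, alpha = 0.05,
                         mode = "weighted_positive",
                         p_method = "asymptotic", p_adjust = "none",
                         min_neurons = 4, metric = "degree_norm",
                         normalize_method = "minmax", bin_width_s = 100,
                         test = "t_test") {
  as_ts <- function(cfg, stage) {
    if (inherits(cfg, "trace_set")) return(cfg)
    if (inherits(cfg, "sim_config")) return(simulate_traceset(cfg))
    abort(sprintf("pipeline stage '%s': input must be a sim_config or trace_set", stage))
  }
  run_one <- function(cfg, stage) {
    ts <- as_ts(cfg, stage)
    norm <- normalize_traces(ts, method = normalize_method)
    events <- detect_events(norm)
    raster <- bin_raster(events, bin_width_s = bin_width_s)
    net <- build_network(norm, alpha = alpha, mode = mode,
                         p_method = p_method, p_adjust = p_adjust)
    dc <- if (!is.null(net$centroids)) distance_control(net) else NULL
    list(trace_set = ts, raster = raster, network = net,
         distance_control = dc)
  }

  a <- run_one(cfg_a, "condition_a")
  b <- run_one(cfg_b, "condition_b")

  nets <- exclude_small_networks(list(a$network, b$network),
                                 min_neurons = min_neurons)
  if (length(nets) < 2) {
    abort("pipeline stage 'exclude_small_networks': fewer than two networks remain for comparison")
  }

  ma <- network_metrics(a$network)
  mb <- network_metrics(b$network)
  cmp <- compare_conditions(ma, mb, metric = metric, test = test)
  cmp$condition_a <- a$network$condition
  cmp$condition_b <- b$network$condition

  manifest <- list(
    package_version = as.character(utils::packageVersion("synconnect")),
    config_a = if (inherits(cfg_a, "sim_config")) unclass(cfg_a) else "user trace_set",
    config_b = if (inherits(cfg_b, "sim_config")) unclass(cfg_b) else "user trace_set",
    alpha = alpha, mode = mode, p_method = p_method, p_adjust = p_adjust,
    min_neurons = min_neurons, metric = metric,
    normalize_method = normalize_method, bin_width_s = bin_width_s,
    test = test
  )

  structure(
    list(
      trace_sets = list(a = a$trace_set, b = b$trace_set),
      rasters = list(a = a$raster, b = b$raster),
      networks = list(a = a$network, b = b$network),
      metrics = list(a = ma, b = mb),
      distance_controls = list(a = a$distance_control, b = b$distance_control),
      comparison = cmp,
      manifest = manifest
    ),
    class = "synconnect_bundle"
  )
}

#' @export
print.synconnect_bundle <- function(x, ...) {
  cat("<synconnect_bundle>\n")
  ga <- glance(x$networks$a)
  gb <- glance(x$networks$b)
  cat(sprintf("  a (%s): %d neurons, %d edges, density %.3f\n",
              ga$condition, ga$n_neurons, ga$n_edges, ga$density))
  cat(sprintf("  b (%s): %d neurons, %d edges, density %.3f\n",
              gb$condition, gb$n_neurons, gb$n_edges, gb$density))
  cat(sprintf("  %s: mean a %.4f vs b %.4f, t = %.3f, p = %.3g\n",
              x$comparison$label, x$comparison$mean_a, x$comparison$mean_b,
              x$comparison$statistic, x$comparison$p_value))
  invisible(x)
}

#' @method glance synconnect_bundle
#' @export
glance.synconnect_bundle <- function(x, ...) x$comparison
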