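#' Plot stacked normalized traces
#'
#' @param object A [trace_set()].
#' @param offset Vertical offset between traces (default 1.2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trace_set
#' @export
autoplot.trace_set <- function(object, offset = 1.2, ...) {
  d <- tidy(object)
  d$y <- d$fluorescence + (d$neuron - 1) * offset
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$y,
                                  group = .data$neuron)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "neuron (stacked fluorescence)") +
    ggplot2::theme_minimal()
}

#' Plot a binned event raster
#'
#' @param object An `event_raster` from [bin_raster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_raster
#' @export
autoplot.event_raster <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start_s, y = .data$neuron,
                                  fill = .data$count)) +
    ggplot2::geom_tile(width = object$bin_width_s) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "neuron", fill = "events") +
    ggplot2::theme_minimal()
}

#' Plot the gated adjacency matrix
#'
#' Tiles are 1 (connected) where the pair's Spearman correlation passed the
#' significance gate, 0 otherwise.
#'
#' @param object A `correlation_network`.
#' @param what `"A"` (adjacency, default), `"W"` (gated weights) or
#'   `"rho"` (raw correlations).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_network
#' @export
autoplot.correlation_network <- function(object, what = c("A", "W", "rho"),
                                         ...) {
  what <- match.arg(what)
  m <- object[[what]]
  d <- tibble(
    from = rep.int(seq_len(nrow(m)), ncol(m)),
    to = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "neuron", y = "neuron", fill = what) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot per-node metric distributions for one or more networks
#'
#' @param object A `network_metrics` object.
#' @param metric Node column to plot (default `"degree_norm"`).
#' @param bins Histogram bin count (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_metrics
#' @export
autoplot.network_metrics <- function(object, metric = "degree_norm",
                                     bins = 10, ...) {
  d <- object$nodes
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = metric, y = "nodes") +
    ggplot2::theme_minimal()
}

#' Plot the distance-versus-correlation control
#'
#' @param object A `distance_control` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_control
#' @export
autoplot.distance_control <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$distance_um, y = .data$rho)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = "inter-centroid distance (µm)",
      y = "Spearman rho",
      subtitle = sprintf("association rho = %s, p = %s",
                         format(object$estimate, digits = 3),
                         format(object$p_value, digits = 3))
    ) +
    ggplot2::theme_minimal()
}
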