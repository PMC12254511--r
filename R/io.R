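#' Write and read trace sets as flat CSV
#'
#' The CSV layout is one row per neuron: columns `x`, `y` hold the ROI
#' centroid (micrometres, `NA` when absent) and the remaining columns hold
#' the frames. The frame rate, condition and region are stored in a header
#' comment line (`# frame_rate=...`), which `read_trace_csv()` parses back.
#'
#' @param ts A [trace_set()].
#' @param path Output file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [trace_set()].
#' @export
write_trace_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  cent <- ts$centroids %||% tibble(x = rep(NA_real_, nrow(ts$traces)),
                                   y = rep(NA_real_, nrow(ts$traces)))
  df <- cbind(as.data.frame(cent[, c("x", "y")]), as.data.frame(ts$traces))
  names(df) <- c("x", "y", paste0("f", seq_len(ncol(ts$traces))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate=%g condition=%s region=%s",
                     ts$frame_rate, ts$condition, ts$region_label), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  frame_rate <- 20
  condition <- NA_character_
  region <- NA_character_
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      val <- parts[2]
      switch(parts[1],
        frame_rate = frame_rate <- as.numeric(val),
        condition = condition <- val,
        region = region <- val
      )
    }
  }
  df <- read.csv(path, comment.char = "#")
  stopifnot(all(c("x", "y") %in% names(df)))
  traces <- as.matrix(df[, setdiff(names(df), c("x", "y")), drop = FALSE])
  centroids <- if (all(is.na(df$x))) NULL else tibble(x = df$x, y = df$y)
  trace_set(traces, frame_rate, centroids,
            condition = condition, region_label = region)
}

#' Write and read patch-clamp sweeps as CSV
#'
#' Layout: header comment with mode/protocol/segment marks, then columns
#' `time,signal[,command]`.
#'
#' @param sweep A [sweep_record()].
#' @param path File path.
#' @return `write_sweep_csv()` returns `path` invisibly; `read_sweep_csv()`
#'   returns a [sweep_record()].
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_record"))
  marks <- sweep$segment_marks
  marks_str <- if (is.null(marks)) "" else {
    paste(sprintf("%s:%g", names(marks), marks), collapse = ";")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s protocol=%s marks=%s",
                     sweep$mode, sweep$protocol, marks_str), con)
  write.csv(as.data.frame(sweep$data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  mode <- "current_clamp"
  protocol <- "spontaneous"
  marks <- NULL
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]*", hdr))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      val <- if (length(parts) > 1) parts[2] else ""
      switch(parts[1],
        mode = mode <- val,
        protocol = protocol <- val,
        marks = if (nzchar(val)) {
          pieces <- strsplit(strsplit(val, ";")[[1]], ":")
          marks <- setNames(
            vapply(pieces, function(p) as.numeric(p[2]), numeric(1)),
            vapply(pieces, `[`, character(1), 1)
          )
        }
      )
    }
  }
  df <- read.csv(path, comment.char = "#")
  sweep_record(df$time, df$signal, mode = mode, command = df$command,
               protocol = protocol, segment_marks = marks)
}

#' Export network matrices as CSV files
#'
#' Writes the four matrices of a gated network (`rho`, `p`, `A`, `W`) as
#' plain CSV files `<prefix>_rho.csv` etc.
#'
#' @param net A `correlation_network`.
#' @param prefix Path prefix for the output files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_network_matrices <- function(net, prefix) {
  stopifnot(inherits(net, "correlation_network"))
  paths <- character(0)
  for (m in c("rho", "p", "A", "W")) {
    p <- paste0(prefix, "_", m, ".csv")
    write.csv(net[[m]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a gated network for graph tools
#'
#' `export_graphml()` writes GraphML via the igraph package;
#' `export_gexf()` writes a minimal GEXF 1.2 file (importable by Gephi)
#' directly. Both encode the undirected significant edges with the Spearman
#' rho as the edge weight and the node ids as labels.
#'
#' @param net A `correlation_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for GraphML export")
  }
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_gexf <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  edges <- tidy(net)
  ids <- rownames(net$A) %||% paste0("n", seq_len(net$n_neurons))
  nodes_xml <- paste(
    sprintf('      <node id="%d" label="%s"/>', seq_len(net$n_neurons), ids),
    collapse = "\n"
  )
  edges_xml <- if (nrow(edges) == 0) "" else paste(
    sprintf('      <edge id="%d" source="%d" target="%d" weight="%.6f"/>',
            seq_len(nrow(edges)), edges$from, edges$to, edges$weight),
    collapse = "\n"
  )
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">\n',
    '  <graph mode="static" defaultedgetype="undirected">\n',
    "    <nodes>\n", nodes_xml, "\n    </nodes>\n",
    "    <edges>\n", edges_xml, "\n    </edges>\n",
    "  </graph>\n</gexf>\n"
  )
  writeLines(xml, path)
  invisible(path)
}
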