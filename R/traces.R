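#' Normalize fluorescence traces per neuron
#'
#' Applies a per-neuron normalization to a trace set. All downstream network
#' statistics are Spearman rank correlations, which are invariant to any
#' per-neuron monotone transform, so the choice of method affects display
#' only, not connectivity.
#'
#' * `"minmax"` — affine map of each trace onto \[0, 1\].
#' * `"zscore"` — mean 0, sd 1 per trace.
#' * `"dff"` — \eqn{\Delta F / F_0} with the baseline \eqn{F_0} taken as a
#'   low percentile of the trace (default 10th).
#'
#' A constant trace cannot be min-max scaled; it is flagged with a warning
#' and mapped to all zeros, and the neuron is retained.
#'
#' @param ts A [trace_set()].
#' @param method `"minmax"` (default), `"zscore"`, or `"dff"`.
#' @param baseline_percentile Baseline quantile for `"dff"`, in \[0, 1\]
#'   (default 0.1).
#' @return A [trace_set()] with normalized traces.
#' @export
normalize_traces <- function(ts, method = c("minmax", "zscore", "dff"),
                             baseline_percentile = 0.1) {
  stopifnot(inherits(ts, "trace_set"))
  method <- match.arg(method)
  x <- ts$traces
  out <- t(apply(x, 1, function(v) {
    switch(method,
      minmax = {
        r <- range(v)
        if (r[1] == r[2]) return(rep(0, length(v)))
        (v - r[1]) / (r[2] - r[1])
      },
      zscore = {
        s <- sd(v)
        if (s == 0) return(rep(0, length(v)))
        (v - mean(v)) / s
      },
      dff = {
        f0 <- quantile(v, baseline_percentile, names = FALSE)
        if (f0 == 0) f0 <- .Machine$double.eps
        (v - f0) / abs(f0)
      }
    )
  }))
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const)) {
    warn(sprintf("%d constant trace(s) mapped to zeros: %s",
                 sum(const), paste(which(const), collapse = ", ")))
  }
  dimnames(out) <- dimnames(x)
  ts$traces <- out
  ts
}

#' Detect fluorescence events by robust threshold crossing
#'
#' An event is an upward crossing of `baseline + threshold_sd * robust_sd`,
#' where the baseline is the per-trace median and the robust sd is
#' 1.4826 x MAD (consistent with the Gaussian sd under pure noise). Runs of
#' consecutive supra-threshold frames are merged into a single event stamped
#' at the onset frame. Median/MAD are used rather than mean/sd because
#' calcium transients skew moment-based baselines upward.
#'
#' @param ts A [trace_set()].
#' @param threshold_sd Threshold in robust-sd units above baseline
#'   (default 2.5).
#' @return A tibble of class `event_table` with columns `neuron`, `frame`,
#'   `time_s`; attributes carry the recording duration and neuron count for
#'   downstream binning.
#' @export
detect_events <- function(ts, threshold_sd = 2.5) {
  stopifnot(inherits(ts, "trace_set"), threshold_sd > 0)
  x <- ts$traces
  ev <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    thr <- median(v) + threshold_sd * mad(v)
    above <- v > thr
    onset <- which(above & !c(FALSE, above[-length(above)]))
    tibble(neuron = i, frame = onset)
  })
  if (nrow(ev) == 0) ev <- tibble(neuron = integer(0), frame = integer(0))
  ev$time_s <- (ev$frame - 1) / ts$frame_rate
  structure(
    as_tibble(ev),
    class = c("event_table", class(tibble())),
    duration_s = ncol(x) / ts$frame_rate,
    n_neurons = nrow(x)
  )
}

#' Bin events into a raster
#'
#' Counts events per neuron in consecutive half-open time bins
#' `[lo, hi)`; the final partial bin is retained, so a 250-s recording
#' binned at 100 s yields bins of 100, 100 and 50 s.
#'
#' @param events An `event_table` from [detect_events()], or any data frame
#'   with `neuron` and `time_s` columns (supply `duration_s` / `n_neurons`
#'   in that case).
#' @param bin_width_s Bin width in seconds (default 100).
#' @param duration_s Recording duration; taken from the event table's
#'   attribute when available.
#' @param n_neurons Number of neurons; taken from the attribute when
#'   available.
#' @return An object of class `event_raster`: event-count matrix
#'   (neurons x bins), `bin_edges` (seconds), `bin_width_s`.
#' @export
bin_raster <- function(events, bin_width_s = 100, duration_s = NULL,
                       n_neurons = NULL) {
  stopifnot(bin_width_s > 0, all(c("neuron", "time_s") %in% names(events)))
  duration_s <- duration_s %||% attr(events, "duration_s")
  n_neurons <- n_neurons %||% attr(events, "n_neurons")
  if (is.null(duration_s) || is.null(n_neurons)) {
    abort("duration_s and n_neurons must be supplied when not carried by the event table")
  }
  n_bins <- ceiling(duration_s / bin_width_s)
  edges <- c(bin_width_s * (seq_len(n_bins) - 1), duration_s)
  counts <- matrix(0L, nrow = n_neurons, ncol = n_bins)
  if (nrow(events) > 0) {
    bin <- pmin(n_bins, floor(events$time_s / bin_width_s) + 1L)
    for (k in seq_along(bin)) {
      counts[events$neuron[k], bin[k]] <- counts[events$neuron[k], bin[k]] + 1L
    }
  }
  structure(
    list(counts = counts, bin_edges = edges, bin_width_s = bin_width_s,
         duration_s = duration_s),
    class = "event_raster"
  )
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d neurons x %d bins (%g-s bins over %g s)\n",
              nrow(x$counts), ncol(x$counts), x$bin_width_s, x$duration_s))
  invisible(x)
}

#' @method tidy event_raster
#' @export
tidy.event_raster <- function(x, ...) {
  n <- nrow(x$counts)
  b <- ncol(x$counts)
  tibble(
    neuron = rep.int(seq_len(n), b),
    bin = rep(seq_len(b), each = n),
    bin_start_s = rep(x$bin_edges[seq_len(b)], each = n),
    count = as.integer(x$counts)
  )
}
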