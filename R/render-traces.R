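#' Construct a trace set
#'
#' Container for a neuron-by-frame fluorescence matrix with per-neuron ROI
#' centroids and acquisition metadata. Most users will obtain one from
#' [simulate_traceset()] or [read_trace_csv()] rather than calling this
#' directly.
#'
#' @param traces Numeric matrix, neurons in rows, frames in columns. No
#'   missing values allowed.
#' @param frame_rate Frames per second.
#' @param centroids Data frame with columns `x`, `y` (micrometres), one row
#'   per neuron, or `NULL`.
#' @param condition Condition label (free text; `"control"` /
#'   `"hyperconnected"` for synthetic data).
#' @param region_label Free-text region label, e.g. `"SNc"` or `"VTA"`.
#' @param spikes Optional `spike_train_set` ground truth (synthetic data).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, frame_rate, centroids = NULL,
                      condition = NA_character_, region_label = NA_character_,
                      spikes = NULL) {
  traces <- as.matrix(traces)
  stopifnot(is.numeric(traces), frame_rate > 0, !anyNA(traces))
  if (!is.null(centroids)) {
    centroids <- as_tibble(centroids)
    stopifnot(all(c("x", "y") %in% names(centroids)),
              nrow(centroids) == nrow(traces))
  }
  if (is.null(rownames(traces))) {
    rownames(traces) <- paste0("n", seq_len(nrow(traces)))
  }
  structure(
    list(traces = traces, frame_rate = frame_rate, centroids = centroids,
         condition = condition, region_label = region_label, spikes = spikes),
    class = "trace_set"
  )
}

#' Render fluorescence traces from spike trains
#'
#' Converts latent spike trains into an imaged fluorescence matrix: each
#' spike train is convolved with the calibrated indicator kernel at the
#' kernel's internal resolution (default 0.5 ms), the high-resolution signal
#' is downsampled to the imaging frame rate by bin averaging, and i.i.d.
#' Gaussian noise of standard deviation `cfg$noise_sd` is added per frame.
#' ROI centroids are placed uniformly at random in the field, independent of
#' ensemble membership, so any spatial structure in downstream correlations
#' is spurious by construction.
#'
#' @param spikes A `spike_train_set` from [simulate_spikes()].
#' @param cfg The same [sim_config()] used to generate the spikes.
#' @return A [trace_set()] with dimensions
#'   `n_neurons x (duration_s * frame_rate)` and the ground-truth spikes
#'   attached.
#' @export
render_traces <- function(spikes, cfg) {
  stopifnot(inherits(spikes, "spike_train_set"), inherits(cfg, "sim_config"))
  res_hz <- 1000 / cfg$kernel$resolution_ms
  if (cfg$frame_rate >= res_hz) {
    abort("frame_rate must be below the kernel's internal resolution rate (downsampling only)")
  }
  spf <- res_hz / cfg$frame_rate
  if (abs(spf - round(spf)) > 1e-8) {
    abort("internal resolution rate must be an integer multiple of frame_rate")
  }
  spf <- as.integer(round(spf))
  n_frames <- as.integer(floor(cfg$duration_s * cfg$frame_rate + 1e-9))
  n_hi <- n_frames * spf
  dt_s <- 1 / res_hz

  # kernel samples out to where the response is negligible
  k_len <- ceiling((cfg$kernel$t_peak_ms + 10 * cfg$kernel$tau_decay_ms) /
                     cfg$kernel$resolution_ms)
  k <- kernel_eval(cfg$kernel, (seq_len(k_len) - 1) * cfg$kernel$resolution_ms)

  clean <- matrix(0, nrow = cfg$n_neurons, ncol = n_frames)
  for (i in seq_len(cfg$n_neurons)) {
    tt <- spikes$spikes[[i]]
    hi <- numeric(n_hi)
    if (length(tt) > 0) {
      idx <- pmin(n_hi, floor(tt / dt_s) + 1L)
      for (j in idx) {
        span <- j:min(n_hi, j + k_len - 1L)
        hi[span] <- hi[span] + k[seq_along(span)]
      }
    }
    clean[i, ] <- colMeans(matrix(hi, nrow = spf))
  }

  noisy <- with_seed(seed_child(cfg$seed, 4), {
    clean + matrix(rnorm(length(clean), 0, cfg$noise_sd),
                   nrow = nrow(clean))
  })
  centroids <- with_seed(seed_child(cfg$seed, 5), {
    tibble(
      x = runif(cfg$n_neurons, 0, cfg$field_size_um[1]),
      y = runif(cfg$n_neurons, 0, cfg$field_size_um[2])
    )
  })

  trace_set(noisy, cfg$frame_rate, centroids,
            condition = cfg$condition, region_label = cfg$region_label,
            spikes = spikes)
}

#' Simulate a complete synthetic imaging field
#'
#' Convenience wrapper: [simulate_spikes()] then [render_traces()].
#'
#' @param cfg A [sim_config()].
#' @return A [trace_set()].
#' @examples
#' ts <- simulate_traceset(sim_config(seed = 1, n_neurons = 5, duration_s = 30))
#' dim(ts$traces)
#' @export
simulate_traceset <- function(cfg) {
  render_traces(simulate_spikes(cfg), cfg)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %d neurons x %d frames @ %g fps (%s%s)\n",
    nrow(x$traces), ncol(x$traces), x$frame_rate,
    if (is.na(x$region_label)) "?" else x$region_label,
    if (is.na(x$condition)) "" else paste0(", ", x$condition)
  ))
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$traces)

#' Long-format view of a trace set
#'
#' @param x A `trace_set`.
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `frame`, `time_s`, `fluorescence`.
#' @method tidy trace_set
#' @export
tidy.trace_set <- function(x, ...) {
  n <- nrow(x$traces)
  f <- ncol(x$traces)
  tibble(
    neuron = rep.int(seq_len(n), f),
    frame = rep(seq_len(f), each = n),
    time_s = rep((seq_len(f) - 1) / x$frame_rate, each = n),
    fluorescence = as.vector(x$traces)
  )
}

#' @method glance trace_set
#' @export
glance.trace_set <- function(x, ...) {
  tibble(
    n_neurons = nrow(x$traces), n_frames = ncol(x$traces),
    frame_rate = x$frame_rate,
    duration_s = ncol(x$traces) / x$frame_rate,
    condition = x$condition, region_label = x$region_label
  )
}
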