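#' Describe a co-active neuronal ensemble
#'
#' An ensemble is a set of neurons that share latent activation events: the
#' events arrive as a Poisson process at `rate_hz`, and at each event every
#' member fires one extra spike with probability `participation`. Shared
#' events are the sole source of correlation between neurons in the
#' generator, emulating synchronous network activity on top of independent
#' pacemaking.
#'
#' @param members Integer indices of the member neurons.
#' @param rate_hz Rate of shared latent events, Hz.
#' @param participation Probability in \[0, 1\] that a member fires at an
#'   event.
#' @return A list of class `sc_ensemble`.
#' @export
ensemble <- function(members, rate_hz, participation) {
  stopifnot(length(members) >= 1, all(members >= 1), rate_hz >= 0,
            participation >= 0, participation <= 1)
  structure(
    list(members = as.integer(members), rate_hz = rate_hz,
         participation = participation),
    class = "sc_ensemble"
  )
}

#' Simulation configuration for synthetic calcium-imaging fields
#'
#' Bundles every parameter of the synthetic recording generator. Defaults
#' emulate the imaging conditions of the study the pipeline targets: 250-s
#' recordings at 20 frames/s of spontaneously pacemaking midbrain dopamine
#' neurons expressing a fast calcium indicator (kernel half-rise 6.6 ms,
#' half-decay 87 ms), with regions of interest placed uniformly at random in
#' the imaged field, independent of correlation structure.
#'
#' Two named conditions are supported. `"control"` fields contain only
#' independent pacemakers (no shared ensembles). `"hyperconnected"` fields
#' add shared latent events: if `ensembles` is not supplied, the field is
#' partitioned into subpopulation ensembles of about 5 neurons, each with
#' shared-event rate 0.5 Hz and participation 0.6, giving positively
#' correlated transients within each subpopulation. Ensemble membership has
#' no relation to ROI position.
#'
#' @param seed Integer seed; every random draw in the generator descends
#'   from it, so identical configurations give bit-identical outputs.
#' @param n_neurons Number of neurons in the field.
#' @param duration_s Recording duration, seconds (default 250).
#' @param frame_rate Imaging frame rate, Hz (default 20; typical range
#'   20-25).
#' @param base_rate_hz Per-neuron background pacemaker rate(s), Hz. Either a
#'   single value, a vector of length `n_neurons`, or `NULL` (the default)
#'   to draw each neuron's rate uniformly from 1-5 Hz.
#' @param jitter_cv Coefficient of variation of background inter-spike
#'   intervals (0 = perfectly regular pacemaking). Default 0.2.
#' @param ensembles List of [ensemble()] objects; see Details.
#' @param kernel A `gcamp_kernel`; default [calibrate_kernel()] with the
#'   6.6 / 87 ms half-times.
#' @param noise_sd Standard deviation of additive Gaussian fluorescence
#'   noise per frame (fluorescence units; kernel peak is 1). Default 0.1.
#' @param field_size_um Width and height of the imaged field in micrometres
#'   for ROI placement. Default `c(300, 300)`.
#' @param condition `"control"` or `"hyperconnected"`.
#' @param region_label Free-text region label (e.g. `"SNc"`, `"VTA"`).
#' @param event_jitter_sd_s Timing jitter (s) applied to each member's spike
#'   around a shared event. Default 0.01.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_neurons, duration_s = 250, frame_rate = 20,
                       base_rate_hz = NULL, jitter_cv = 0.2,
                       ensembles = NULL,
                       kernel = calibrate_kernel(),
                       noise_sd = 0.1, field_size_um = c(300, 300),
                       condition = c("control", "hyperconnected"),
                       region_label = "SNc",
                       event_jitter_sd_s = 0.01) {
  condition <- match.arg(condition)
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    n_neurons >= 1, duration_s > 0, frame_rate > 0,
    jitter_cv >= 0, noise_sd >= 0,
    length(field_size_um) == 2, all(field_size_um > 0),
    inherits(kernel, "gcamp_kernel")
  )
  if (!is.null(base_rate_hz)) {
    stopifnot(length(base_rate_hz) %in% c(1, n_neurons), all(base_rate_hz >= 0))
  }
  if (is.null(ensembles)) {
    # default hyperconnected structure: the field is partitioned into
    # subpopulation ensembles of ~5 neurons, each sharing latent events at
    # 0.5 Hz with participation 0.6; control fields have no ensembles
    ensembles <- if (condition == "hyperconnected") {
      groups <- split(seq_len(n_neurons), ceiling(seq_len(n_neurons) / 5))
      unname(lapply(groups, function(m) {
        ensemble(m, rate_hz = 0.5, participation = 0.6)
      }))
    } else {
      list()
    }
  }
  stopifnot(all(vapply(ensembles, inherits, logical(1), "sc_ensemble")))
  for (e in ensembles) {
    if (max(e$members) > n_neurons) {
      abort("ensemble member index exceeds n_neurons")
    }
  }
  if (condition == "control" &&
      any(vapply(ensembles, function(e) e$participation > 0 && e$rate_hz > 0,
                 logical(1)))) {
    abort("control condition must have no active ensembles (participation or rate must be 0)")
  }
  if (condition == "hyperconnected" && length(ensembles) > 0 &&
      all(vapply(ensembles, function(e) e$participation == 0, logical(1)))) {
    warn("hyperconnected condition with zero participation everywhere: no correlation will be generated")
  }

  structure(
    list(
      seed = as.integer(seed), n_neurons = as.integer(n_neurons),
      duration_s = duration_s, frame_rate = frame_rate,
      base_rate_hz = base_rate_hz, jitter_cv = jitter_cv,
      ensembles = ensembles, kernel = kernel, noise_sd = noise_sd,
      field_size_um = field_size_um, condition = condition,
      region_label = region_label, event_jitter_sd_s = event_jitter_sd_s
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d neurons, %.0f s @ %g fps, condition '%s', %d ensemble(s), seed %d\n",
    x$n_neurons, x$duration_s, x$frame_rate, x$condition,
    length(x$ensembles), x$seed
  ))
  invisible(x)
}
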