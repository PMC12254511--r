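#' Detect action potentials by threshold crossing
#'
#' Marks a spike at each upward crossing of the voltage threshold,
#' enforcing a refractory separation so multi-sample crossings of a single
#' spike are not double counted.
#'
#' @param sweep A current-clamp [sweep_record()].
#' @param threshold_mv Voltage threshold, mV (default -20).
#' @param refractory_ms Minimum separation between spikes, ms (default 2).
#' @return Numeric vector of spike times (seconds, at the crossing sample).
#' @export
detect_spikes <- function(sweep, threshold_mv = -20, refractory_ms = 2) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (sweep$mode != "current_clamp") {
    abort("spike detection requires a current-clamp sweep")
  }
  v <- sweep$data$signal
  cross <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv) + 1L
  if (length(cross) == 0) return(numeric(0))
  times <- sweep$data$time[cross]
  # greedy refractory merge: drop any crossing closer than the refractory
  # period to the last *kept* crossing
  out <- times[1]
  for (t in times[-1]) {
    if (t - out[length(out)] >= refractory_ms / 1000) out <- c(out, t)
  }
  out
}

#' Action potential half-width
#'
#' Width of a spike at half its amplitude. The local baseline is the median
#' voltage over the 10 ms preceding the threshold crossing; the amplitude
#' is peak minus baseline, and the width is measured between the rising and
#' falling crossings of the half-amplitude level, each located by linear
#' interpolation between samples.
#'
#' @param sweep A current-clamp [sweep_record()].
#' @param spike_time Spike time (s), e.g. from [detect_spikes()].
#' @param window_ms Search window after the crossing for the peak and the
#'   falling flank, ms (default 10).
#' @param baseline_ms Pre-crossing window for the baseline, ms (default 10).
#' @return Half-width in milliseconds, or `NA` if the peak does not exceed
#'   the baseline.
#' @export
half_width <- function(sweep, spike_time, window_ms = 10, baseline_ms = 10) {
  stopifnot(inherits(sweep, "sweep_record"))
  tt <- sweep$data$time
  v <- sweep$data$signal
  sr <- sweep$sample_rate_hz
  i0 <- which.min(abs(tt - spike_time))

  b0 <- max(1, i0 - round(baseline_ms / 1000 * sr))
  # median, not mean: the window may clip the foot of the rising flank
  base <- median(v[b0:max(b0, i0 - 1)])
  i1 <- min(length(v), i0 + round(window_ms / 1000 * sr))
  seg <- i0:i1
  ipk <- seg[which.max(v[seg])]
  peak <- v[ipk]
  if (peak <= base) return(NA_real_)
  half <- base + (peak - base) / 2

  # rising crossing: walk back from the peak
  iu <- ipk
  while (iu > 1 && v[iu - 1] > half) iu <- iu - 1
  if (iu == 1 || v[iu - 1] > half) return(NA_real_)
  t_up <- tt[iu - 1] + (half - v[iu - 1]) / (v[iu] - v[iu - 1]) * (tt[iu] - tt[iu - 1])

  # falling crossing: walk forward from the peak
  id <- ipk
  while (id < length(v) && v[id + 1] > half) id <- id + 1
  if (id == length(v)) return(NA_real_)
  t_dn <- tt[id] + (v[id] - half) / (v[id] - v[id + 1]) * (tt[id + 1] - tt[id])

  (t_dn - t_up) * 1000
}

#' Firing statistics for a single sweep or segment
#'
#' @param sweep A current-clamp [sweep_record()].
#' @param threshold_mv,refractory_ms Spike-detection parameters.
#' @return A one-row tibble: `n_spikes`, `duration_s`, `rate_hz`, and the
#'   mean AP half-width (`half_width_ms`) over detected spikes.
#' @export
spike_stats <- function(sweep, threshold_mv = -20, refractory_ms = 2) {
  spk <- detect_spikes(sweep, threshold_mv, refractory_ms)
  dur <- nrow(sweep$data) / sweep$sample_rate_hz
  hw <- if (length(spk)) {
    mean(vapply(spk, function(s) half_width(sweep, s), numeric(1)),
         na.rm = TRUE)
  } else {
    NA_real_
  }
  tibble(n_spikes = length(spk), duration_s = dur,
         rate_hz = length(spk) / dur, half_width_ms = hw)
}

#' Resilience to a prolonged hyperpolarization challenge
#'
#' Quantifies how well a neuron's spontaneous firing recovers after being
#' held hyperpolarized: firing frequency is measured in the pre-challenge
#' baseline segment and the post-challenge recovery segment (spikes during
#' the hyperpolarized segment are excluded), and the resilience statistic
#' is the percent change
#' \deqn{100 \times (f_{post} - f_{pre}) / f_{pre}.}
#' A value near 0 indicates full recovery; strongly negative values
#' indicate impaired recovery. When no baseline spikes are present the
#' percent change is undefined and the record is flagged.
#'
#' @param sweep A `hyperpolarization_challenge` [sweep_record()] whose
#'   `segment_marks` name `baseline_end`, `hyper_end` and `end`.
#' @param threshold_mv,refractory_ms Spike-detection parameters.
#' @return A one-row tibble: `f_pre_hz`, `f_post_hz`, `percent_change`,
#'   spike counts per segment, and a `flagged` logical (no baseline
#'   firing).
#' @export
challenge_resilience <- function(sweep, threshold_mv = -20, refractory_ms = 2) {
  stopifnot(inherits(sweep, "sweep_record"))
  marks <- sweep$segment_marks
  if (is.null(marks) ||
      !all(c("baseline_end", "hyper_end", "end") %in% names(marks))) {
    abort("sweep must carry segment_marks 'baseline_end', 'hyper_end', 'end'")
  }
  spk <- detect_spikes(sweep, threshold_mv, refractory_ms)
  pre <- spk[spk < marks["baseline_end"]]
  post <- spk[spk >= marks["hyper_end"] & spk < marks["end"]]
  dur_pre <- unname(marks["baseline_end"])
  dur_post <- unname(marks["end"] - marks["hyper_end"])
  f_pre <- length(pre) / dur_pre
  f_post <- length(post) / dur_post
  pct <- if (f_pre > 0) 100 * (f_post - f_pre) / f_pre else NA_real_
  if (f_pre == 0) {
    warn("no baseline spikes: percent change undefined, neuron flagged")
  }
  tibble(
    f_pre_hz = f_pre, f_post_hz = f_post, percent_change = pct,
    n_pre = length(pre), n_post = length(post), flagged = f_pre == 0
  )
}

#' Membrane capacitance from a voltage-clamp ramp
#'
#' Estimates membrane capacitance from the current separation between the
#' rising and falling limbs of a triangular voltage ramp (hold −70 mV,
#' down 10 mV over 50 ms, back over 50 ms in the default protocol).
#' During the down ramp the capacitive current is \eqn{-C_m |dV/dt|};
#' during the up ramp it is \eqn{+C_m |dV/dt|}, while the leak current is
#' identical at matched voltages. Averaging the current over the central
#' portion of each limb (where dV/dt is constant and clamp transients have
#' settled) and subtracting therefore cancels the leak and leaves twice the
#' capacitive current:
#' \deqn{C_m = \frac{\Delta I}{2\,(dV/dT)}.}
#' Because the commanded voltage changes gradually rather than stepwise,
#' the estimate is insensitive to series (access) resistance.
#'
#' @param sweep A `capacitance_ramp` voltage-clamp [sweep_record()] with a
#'   command waveform.
#' @param central_fraction Fraction of each limb, centred on its midpoint,
#'   over which currents are averaged (default 0.5).
#' @return A one-row tibble: `cm_pf`, `di_pa` (rising-minus-falling current
#'   separation), `dv_mv`, `dt_ms`, `dvdt_v_per_s`, `central_fraction`.
#' @export
estimate_capacitance <- function(sweep, central_fraction = 0.5) {
  stopifnot(inherits(sweep, "sweep_record"),
            central_fraction > 0, central_fraction <= 1)
  if (sweep$mode != "voltage_clamp" || sweep$protocol != "capacitance_ramp" ||
      is.null(sweep$data$command)) {
    abort("capacitance estimation requires a voltage-clamp capacitance_ramp sweep with a command waveform")
  }
  cmd <- sweep$data$command
  i_pa <- sweep$data$signal
  dt_s <- 1 / sweep$sample_rate_hz
  slope <- diff(cmd) / dt_s / 1000            # V/s per inter-sample step

  runs <- rle(sign(round(slope, 10)))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  down <- which(runs$values < 0)[1]
  up <- which(runs$values > 0)[1]
  if (is.na(down) || is.na(up)) {
    abort("command waveform does not contain both a falling and a rising ramp limb")
  }

  central_mean <- function(run_idx) {
    # samples spanned by the limb (slope index k joins samples k and k+1)
    lo <- starts[run_idx]
    hi <- ends[run_idx] + 1
    len <- hi - lo + 1
    drop <- floor(len * (1 - central_fraction) / 2)
    sel <- (lo + drop):(hi - drop)
    c(mean(i_pa[sel]), mean(abs(slope[lo:ends[run_idx]])))
  }
  dn <- central_mean(down)
  up_ <- central_mean(up)
  dvdt <- (dn[2] + up_[2]) / 2                # V/s
  di <- up_[1] - dn[1]                         # pA (rising minus falling limb)

  n_limb <- runs$lengths[down]
  tibble(
    cm_pf = di / (2 * dvdt),
    di_pa = di,
    dv_mv = abs(sum(slope[starts[down]:ends[down]])) * dt_s * 1000,
    dt_ms = n_limb * dt_s * 1000,
    dvdt_v_per_s = dvdt,
    central_fraction = central_fraction
  )
}
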