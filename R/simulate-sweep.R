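#' Construct a patch-clamp sweep
#'
#' A sweep is a uniformly sampled electrophysiological record: membrane
#' voltage (mV) in current clamp or membrane current (pA) in voltage clamp,
#' optionally with the commanded waveform, plus named segment boundaries.
#'
#' @param time Time vector, seconds, strictly increasing and uniform.
#' @param signal Recorded signal: mV (current clamp) or pA (voltage clamp).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param command Optional commanded waveform (pA or mV) of the same length.
#' @param protocol One of `"spontaneous"`, `"hyperpolarization_challenge"`,
#'   `"capacitance_ramp"`.
#' @param segment_marks Named numeric vector of time boundaries (seconds)
#'   inside the record, e.g. `c(baseline_end = 30, hyper_end = 60)`.
#' @param ground_truth Optional list of generating parameters (synthetic
#'   sweeps).
#' @return An object of class `sweep_record`.
#' @export
sweep_record <- function(time, signal,
                         mode = c("current_clamp", "voltage_clamp"),
                         command = NULL,
                         protocol = c("spontaneous",
                                      "hyperpolarization_challenge",
                                      "capacitance_ramp"),
                         segment_marks = NULL, ground_truth = NULL) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  stopifnot(length(time) == length(signal), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9 * max(dt)) {
    abort("sweep time must be strictly increasing and uniformly sampled")
  }
  if (!is.null(command)) stopifnot(length(command) == length(signal))
  if (!is.null(segment_marks)) {
    stopifnot(!is.null(names(segment_marks)),
              all(segment_marks >= time[1]),
              all(segment_marks <= time[length(time)] + dt[1]))
  }
  data <- tibble(time = time, signal = signal)
  if (!is.null(command)) data$command <- command
  structure(
    list(data = data, mode = mode, protocol = protocol,
         sample_rate_hz = 1 / dt[1], segment_marks = segment_marks,
         ground_truth = ground_truth),
    class = "sweep_record"
  )
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf(
    "<sweep_record> %s / %s: %.3g s @ %g kHz\n",
    x$mode, x$protocol,
    nrow(x$data) / x$sample_rate_hz, x$sample_rate_hz / 1000
  ))
  invisible(x)
}

#' @method tidy sweep_record
#' @export
tidy.sweep_record <- function(x, ...) x$data

# Stylized action-potential waveform: a biexponential spikelet
# (1 - exp(-u/a)) * exp(-u/b), time-rescaled so its full width at half
# maximum equals the requested half-width and peak-normalised to 1.
ap_template <- function(half_width_ms, sample_rate_hz) {
  a <- 0.2
  b <- 0.6
  u <- seq(0, 8, by = 0.001)
  s <- (1 - exp(-u / a)) * exp(-u / b)
  s <- s / max(s)
  above <- which(s >= 0.5)
  fwhm_u <- u[above[length(above)]] - u[above[1]]
  scale_ms <- half_width_ms / fwhm_u     # ms of real time per template unit
  dt_ms <- 1000 / sample_rate_hz
  n <- ceiling(8 * scale_ms / dt_ms)
  tt <- (seq_len(n) - 1) * dt_ms / scale_ms
  v <- (1 - exp(-tt / a)) * exp(-tt / b)
  v / max(v)
}

# Jittered-periodic spike times on [0, duration); deterministic phase when
# jitter_cv = 0 so planted spike counts are exact.
pacemaker_times <- function(rate_hz, duration_s, jitter_cv) {
  if (rate_hz <= 0) return(numeric(0))
  mean_isi <- 1 / rate_hz
  if (jitter_cv == 0) {
    return(seq(mean_isi / 2, duration_s - 1e-12, by = mean_isi))
  }
  shape <- 1 / jitter_cv^2
  n_draw <- max(10, ceiling(duration_s * rate_hz * 1.5 + 6 * sqrt(duration_s * rate_hz)))
  tt <- runif(1, 0, mean_isi) + cumsum(rgamma(n_draw, shape, scale = mean_isi / shape))
  while (tt[length(tt)] < duration_s) {
    tt <- c(tt, tt[length(tt)] +
              cumsum(rgamma(n_draw, shape, scale = mean_isi / shape)))
  }
  tt[tt < duration_s]
}

insert_spikes <- function(v, spike_times, template, sample_rate_hz,
                          amplitude_mv) {
  n <- length(v)
  for (ts in spike_times) {
    j <- floor(ts * sample_rate_hz) + 1L
    if (j > n) next
    span <- j:min(n, j + length(template) - 1L)
    v[span] <- v[span] + amplitude_mv * template[seq_along(span)]
  }
  v
}

#' Simulate a stylized patch-clamp sweep
#'
#' Generates synthetic current-clamp or voltage-clamp records for the three
#' protocols the analysis supports.
#'
#' * `"spontaneous"` — current clamp at a resting potential with stylized
#'   action potentials (biexponential spikelets of configurable amplitude
#'   and half-width) inserted at jittered pacemaker times.
#' * `"hyperpolarization_challenge"` — 30 s of free firing, 30 s clamped at
#'   \-100 mV (no spikes), then 30 s of recovery firing whose rate is the
#'   baseline rate times `recovery_multiplier`; a multiplier below 1 models
#'   impaired recovery. Segment boundaries are recorded in `segment_marks`.
#' * `"capacitance_ramp"` — voltage clamp of a single-compartment RC cell,
#'   `I = Cm dV/dt + (V - V_rest)/Rm`, under a triangular command ramp
#'   (hold −70 mV, down to −80 mV over 50 ms, back to −70 mV over
#'   50 ms). Optional series (access) resistance `rs_mohm` low-pass
#'   filters the cell voltage. True `cm_pf` and `rm_mohm` are stored in
#'   `ground_truth`.
#'
#' @param protocol Protocol name (see above).
#' @param seed Integer seed (ignored when nothing is random).
#' @param rate_hz Baseline firing rate, Hz (current-clamp protocols).
#' @param duration_s Duration of a spontaneous sweep, s.
#' @param segment_s Length of each challenge segment, s (default 30).
#' @param recovery_multiplier Post-challenge firing-rate multiplier.
#' @param jitter_cv ISI coefficient of variation (0 = exact planted counts).
#' @param sample_rate_hz Sampling rate, Hz (default 10000).
#' @param baseline_mv Resting potential, mV.
#' @param hyper_mv Holding potential during the challenge segment, mV.
#' @param ap_amplitude_mv Spike amplitude above baseline, mV.
#' @param ap_half_width_ms Spike full width at half maximum, ms.
#' @param noise_sd Additive Gaussian noise sd (mV or pA; default 0).
#' @param cm_pf,rm_mohm,rs_mohm,v_hold_mv,v_rest_mv,ramp_mv,limb_ms,pre_ms,post_ms
#'   Capacitance-ramp cell and command parameters: membrane capacitance
#'   (pF), membrane resistance (megohm, may be `Inf`), series resistance
#'   (megohm), holding potential (mV), cell resting potential (mV), ramp
#'   deviation (mV, negative for a downward ramp), single-limb duration
#'   (ms), and pre/post hold padding (ms).
#' @return A [sweep_record()].
#' @examples
#' sw <- simulate_sweep("capacitance_ramp", cm_pf = 100, rm_mohm = Inf)
#' estimate_capacitance(sw)
#' @export
simulate_sweep <- function(protocol = c("spontaneous",
                                        "hyperpolarization_challenge",
                                        "capacitance_ramp"),
                           seed = 1L,
                           rate_hz = 2, duration_s = 30, segment_s = 30,
                           recovery_multiplier = 1, jitter_cv = 0.1,
                           sample_rate_hz = 10000,
                           baseline_mv = -60, hyper_mv = -100,
                           ap_amplitude_mv = 80, ap_half_width_ms = 1.5,
                           noise_sd = 0,
                           cm_pf = 100, rm_mohm = Inf, rs_mohm = 0,
                           v_hold_mv = -70, v_rest_mv = -70,
                           ramp_mv = -10, limb_ms = 50,
                           pre_ms = 20, post_ms = 20) {
  protocol <- match.arg(protocol)
  dt <- 1 / sample_rate_hz

  if (protocol == "capacitance_ramp") {
    n_pre <- round(pre_ms / 1000 * sample_rate_hz)
    n_limb <- round(limb_ms / 1000 * sample_rate_hz)
    n_post <- round(post_ms / 1000 * sample_rate_hz)
    cmd <- c(
      rep(v_hold_mv, n_pre),
      v_hold_mv + ramp_mv * seq_len(n_limb) / n_limb,
      v_hold_mv + ramp_mv * (1 - seq_len(n_limb) / n_limb),
      rep(v_hold_mv, n_post)
    )
    time <- (seq_along(cmd) - 1) * dt
    if (rs_mohm <= 0) {
      # ideal clamp: cell voltage equals command
      dvdt <- c(0, diff(cmd)) / dt / 1000          # V/s
      leak <- if (is.infinite(rm_mohm)) 0 else (cmd - v_rest_mv) / rm_mohm * 1000  # pA
      i_pa <- cm_pf * dvdt + leak
    } else {
      # series resistance: integrate dVm/dt = ((Vcmd-Vm)/Rs - (Vm-Vrest)/Rm)/Cm
      # units: mV, megohm, pF -> tau in ms; step with exact exponential update
      vm <- numeric(length(cmd))
      vm[1] <- v_hold_mv
      g_s <- 1 / rs_mohm
      g_m <- if (is.infinite(rm_mohm)) 0 else 1 / rm_mohm
      # conductances in uS (1/Mohm), capacitance pF: tau = C/g in pF/uS = us
      tau_us <- cm_pf / (g_s + g_m)
      a <- exp(-(dt * 1e6) / tau_us)
      for (i in 2:length(cmd)) {
        # hold the command at its midpoint value over the step so vm[i]
        # approximates the cell voltage at the sample time, not a half
        # step late (matters for the ramp-current plateau)
        cmd_mid <- (cmd[i - 1] + cmd[i]) / 2
        v_inf <- (g_s * cmd_mid + g_m * v_rest_mv) / (g_s + g_m)
        vm[i] <- v_inf + (vm[i - 1] - v_inf) * a
      }
      i_pa <- (cmd - vm) / rs_mohm * 1000          # mV/Mohm = nA -> pA
    }
    if (noise_sd > 0) {
      i_pa <- with_seed(seed, i_pa + rnorm(length(i_pa), 0, noise_sd))
    }
    marks <- c(ramp_start = n_pre * dt, ramp_mid = (n_pre + n_limb) * dt,
               ramp_end = (n_pre + 2 * n_limb) * dt)
    return(sweep_record(time, i_pa, mode = "voltage_clamp", command = cmd,
                        protocol = "capacitance_ramp", segment_marks = marks,
                        ground_truth = list(cm_pf = cm_pf, rm_mohm = rm_mohm,
                                            rs_mohm = rs_mohm)))
  }

  template <- ap_template(ap_half_width_ms, sample_rate_hz)

  if (protocol == "spontaneous") {
    n <- round(duration_s * sample_rate_hz)
    time <- (seq_len(n) - 1) * dt
    spikes <- with_seed(seed, pacemaker_times(rate_hz, duration_s, jitter_cv))
    v <- insert_spikes(rep(baseline_mv, n), spikes, template,
                       sample_rate_hz, ap_amplitude_mv)
    if (noise_sd > 0) {
      v <- with_seed(seed_child(seed, 1), v + rnorm(n, 0, noise_sd))
    }
    return(sweep_record(time, v, mode = "current_clamp",
                        protocol = "spontaneous",
                        segment_marks = c(end = duration_s),
                        ground_truth = list(spike_times = spikes,
                                            rate_hz = rate_hz)))
  }

  # hyperpolarization challenge: baseline | clamp at hyper_mv | recovery
  n_seg <- round(segment_s * sample_rate_hz)
  time <- (seq_len(3 * n_seg) - 1) * dt
  pre_spikes <- with_seed(seed, pacemaker_times(rate_hz, segment_s, jitter_cv))
  post_spikes <- with_seed(
    seed_child(seed, 2),
    pacemaker_times(rate_hz * recovery_multiplier, segment_s, jitter_cv)
  )
  v_pre <- insert_spikes(rep(baseline_mv, n_seg), pre_spikes, template,
                         sample_rate_hz, ap_amplitude_mv)
  v_post <- insert_spikes(rep(baseline_mv, n_seg), post_spikes, template,
                          sample_rate_hz, ap_amplitude_mv)
  v <- c(v_pre, rep(hyper_mv, n_seg), v_post)
  if (noise_sd > 0) {
    v <- with_seed(seed_child(seed, 3), v + rnorm(length(v), 0, noise_sd))
  }
  sweep_record(
    time, v, mode = "current_clamp", protocol = "hyperpolarization_challenge",
    segment_marks = c(baseline_end = segment_s, hyper_end = 2 * segment_s,
                      end = 3 * segment_s),
    ground_truth = list(pre_spikes = pre_spikes,
                        post_spikes = post_spikes + 2 * segment_s,
                        rate_hz = rate_hz,
                        recovery_multiplier = recovery_multiplier)
  )
}
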