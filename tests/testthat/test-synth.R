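test_that("identical configurations give bit-identical outputs", {
  cfg <- sim_config(seed = 7, n_neurons = 6, duration_s = 30,
                    condition = "hyperconnected")
  ts1 <- simulate_traceset(cfg)
  ts2 <- simulate_traceset(cfg)
  expect_identical(ts1$traces, ts2$traces)
  expect_identical(ts1$centroids, ts2$centroids)
  expect_identical(ts1$spikes$spikes, ts2$spikes$spikes)

  sw1 <- simulate_sweep("hyperpolarization_challenge", seed = 3, noise_sd = 0.5)
  sw2 <- simulate_sweep("hyperpolarization_challenge", seed = 3, noise_sd = 0.5)
  expect_identical(sw1$data, sw2$data)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- runif(3)
  set.seed(42)
  invisible(simulate_traceset(sim_config(seed = 1, n_neurons = 3,
                                         duration_s = 20)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("background spike counts match the configured pacemaker rate", {
  counts <- vapply(1:20, function(s) {
    sts <- simulate_spikes(sim_config(seed = s, n_neurons = 1,
                                      base_rate_hz = 2, jitter_cv = 0.1))
    length(sts$spikes[[1]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - 500), 50)   # 2 Hz x 250 s = 500, within 10%
})

test_that("spike times are sorted, strictly increasing and within range", {
  cfg <- sim_config(seed = 5, n_neurons = 10, duration_s = 50,
                    condition = "hyperconnected")
  sts <- simulate_spikes(cfg)
  for (tt in sts$spikes) {
    expect_true(all(tt >= 0 & tt < cfg$duration_s))
    if (length(tt) > 1) expect_true(all(diff(tt) > 0))
  }
})

test_that("zero participation yields uncorrelated spike counts", {
  cfg <- sim_config(seed = 11, n_neurons = 15, duration_s = 250,
                    base_rate_hz = 3, condition = "control")
  sts <- simulate_spikes(cfg)
  edges <- seq(0, 250, by = 1)
  counts <- t(vapply(sts$spikes,
                     function(tt) hist(tt, edges, plot = FALSE)$counts,
                     numeric(length(edges) - 1)))
  rho <- cor(t(counts))
  expect_lt(abs(mean(rho[upper.tri(rho)])), 0.05)
})

test_that("fully shared events produce strongly correlated counts", {
  cfg <- sim_config(seed = 3, n_neurons = 2, duration_s = 250,
                    base_rate_hz = 2, condition = "hyperconnected",
                    ensembles = list(ensemble(1:2, rate_hz = 1,
                                              participation = 1)))
  sts <- simulate_spikes(cfg)
  edges <- seq(0, 250, by = 1)
  c1 <- hist(sts$spikes[[1]], edges, plot = FALSE)$counts
  c2 <- hist(sts$spikes[[2]], edges, plot = FALSE)$counts
  expect_gt(cor(c1, c2), 0.5)
})

test_that("rendered trace matrix has duration x frame-rate frames", {
  ts <- simulate_traceset(sim_config(seed = 1, n_neurons = 10))
  expect_equal(dim(ts$traces), c(10, 5000))   # 250 s x 20 fps
  expect_equal(nrow(ts$centroids), 10)
})

test_that("an empty spike train renders to pure noise at the configured sd", {
  cfg <- sim_config(seed = 9, n_neurons = 3, duration_s = 100,
                    base_rate_hz = 0, noise_sd = 0.3)
  ts <- simulate_traceset(cfg)
  for (i in 1:3) {
    expect_lt(abs(sd(ts$traces[i, ]) - 0.3), 0.03)
  }
})

test_that("a single spike renders the downsampled kernel without noise", {
  cfg <- sim_config(seed = 2, n_neurons = 1, duration_s = 30,
                    base_rate_hz = 0, noise_sd = 0)
  sts <- structure(
    list(spikes = list(10), rates_hz = 0, n_neurons = 1L, duration_s = 30,
         condition = "control"),
    class = "spike_train_set"
  )
  ts <- render_traces(sts, cfg)
  # oracle: bin-average the densely sampled kernel over one frame
  k <- cfg$kernel
  res_ms <- k$resolution_ms
  hi <- kernel_eval(k, seq(0, 2000, by = res_ms))
  spf <- (1000 / res_ms) / cfg$frame_rate
  frames <- colMeans(matrix(hi[seq_len(spf * floor(length(hi) / spf))],
                            nrow = spf))
  expect_equal(max(ts$traces[1, ]), max(frames), tolerance = 1e-8)
})

test_that("noise-free fluorescence mass equals spike count x kernel area", {
  cfg <- sim_config(seed = 4, n_neurons = 1, duration_s = 60,
                    base_rate_hz = 2, jitter_cv = 0.2, noise_sd = 0)
  sts <- simulate_spikes(cfg)
  sts$spikes[[1]] <- sts$spikes[[1]][sts$spikes[[1]] < 55]  # avoid edge loss
  ts <- render_traces(sts, cfg)
  total <- sum(ts$traces[1, ]) / cfg$frame_rate                 # fluor * s
  expected <- length(sts$spikes[[1]]) * kernel_integral(cfg$kernel) / 1000
  expect_equal(total, expected, tolerance = 0.01)
})

test_that("config validation catches inconsistent settings", {
  expect_error(sim_config(seed = 1, n_neurons = 5, duration_s = -1))
  expect_error(sim_config(seed = 1, n_neurons = 2,
                          ensembles = list(ensemble(1:5, 1, 0.5))))
  expect_error(ensemble(1:2, 1, participation = 1.4))
  expect_error(
    sim_config(seed = 1, n_neurons = 4, condition = "control",
               ensembles = list(ensemble(1:2, 1, 0.5)))
  )
})

test_that("capacitance-ramp sweep follows the analytic RC current", {
  sw <- simulate_sweep("capacitance_ramp", cm_pf = 100, rm_mohm = Inf)
  # 100 pF x 0.2 V/s = 20 pA, opposite signs on the two limbs
  mid_down <- sw$data$signal[sw$data$time > 0.03 & sw$data$time < 0.06]
  mid_up <- sw$data$signal[sw$data$time > 0.08 & sw$data$time < 0.11]
  expect_equal(mean(mid_down), -20, tolerance = 0.01)
  expect_equal(mean(mid_up), 20, tolerance = 0.01)
})

test_that("challenge sweep with multiplier 1 fires equally pre and post", {
  sw <- simulate_sweep("hyperpolarization_challenge", seed = 8,
                       rate_hz = 2, jitter_cv = 0, recovery_multiplier = 1,
                       sample_rate_hz = 2000)
  res <- challenge_resilience(sw)
  expect_equal(res$n_pre, res$n_post)
  expect_equal(res$percent_change, 0)
})

test_that("spontaneous sweep at 2 Hz for 30 s yields about 60 spikes", {
  sw <- simulate_sweep("spontaneous", seed = 12, rate_hz = 2,
                       duration_s = 30, sample_rate_hz = 2000)
  expect_lt(abs(length(detect_spikes(sw)) - 60), 10)
})

test_that("unknown protocols are rejected", {
  expect_error(simulate_sweep("voltage_step"))
})
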