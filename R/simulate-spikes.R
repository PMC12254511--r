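#' Simulate pacemaker spike trains with shared ensemble events
#'
#' Generates the latent ground-truth spiking of a synthetic imaging field.
#' Each neuron fires jittered-periodic background spikes: inter-spike
#' intervals are gamma distributed with mean `1 / rate` and coefficient of
#' variation `jitter_cv` (a renewal model of noisy pacemaking). On top of
#' that, each configured [ensemble()] emits shared latent events as a
#' Poisson process; at each event every member fires one extra spike with
#' its participation probability, jittered by `event_jitter_sd_s`. Shared
#' events are the only source of inter-neuron correlation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `spike_train_set`: a list with `spikes` (list
#'   of sorted spike-time vectors, seconds), `rates_hz` (realised background
#'   rates), and the generating configuration's dimensions.
#' @examples
#' sts <- simulate_spikes(sim_config(seed = 1, n_neurons = 4, duration_s = 30))
#' lengths(sts$spikes)
#' @export
simulate_spikes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_neurons
  dur <- cfg$duration_s

  rates <- with_seed(seed_child(cfg$seed, 1), {
    if (is.null(cfg$base_rate_hz)) {
      runif(n, 1, 5)
    } else {
      rep_len(cfg$base_rate_hz, n)
    }
  })

  spikes <- with_seed(seed_child(cfg$seed, 2), {
    lapply(seq_len(n), function(i) {
      r <- rates[i]
      if (r <= 0) return(numeric(0))
      mean_isi <- 1 / r
      # draw enough intervals to cover the recording with margin
      n_draw <- max(10, ceiling(dur * r * 1.5 + 6 * sqrt(dur * r)))
      isi <- if (cfg$jitter_cv == 0) {
        rep(mean_isi, n_draw)
      } else {
        shape <- 1 / cfg$jitter_cv^2
        rgamma(n_draw, shape = shape, scale = mean_isi / shape)
      }
      t0 <- runif(1, 0, mean_isi)          # random phase
      tt <- t0 + cumsum(isi)
      while (length(tt) > 0 && tt[length(tt)] < dur) {
        extra <- if (cfg$jitter_cv == 0) {
          rep(mean_isi, n_draw)
        } else {
          rgamma(n_draw, shape = 1 / cfg$jitter_cv^2,
                 scale = mean_isi * cfg$jitter_cv^2)
        }
        tt <- c(tt, tt[length(tt)] + cumsum(extra))
      }
      tt[tt < dur]
    })
  })

  if (length(cfg$ensembles) > 0) {
    spikes <- with_seed(seed_child(cfg$seed, 3), {
      for (e in cfg$ensembles) {
        if (e$rate_hz <= 0 || e$participation <= 0) next
        n_ev <- rpois(1, e$rate_hz * dur)
        ev <- sort(runif(n_ev, 0, dur))
        for (i in e$members) {
          fire <- runif(length(ev)) < e$participation
          tt <- ev[fire] + rnorm(sum(fire), 0, cfg$event_jitter_sd_s)
          spikes[[i]] <- c(spikes[[i]], tt[tt >= 0 & tt < dur])
        }
      }
      spikes
    })
  }

  spikes <- lapply(spikes, function(tt) {
    tt <- sort(tt)
    tt[!duplicated(tt)]
  })

  structure(
    list(spikes = spikes, rates_hz = rates, n_neurons = n,
         duration_s = dur, condition = cfg$condition),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d neurons over %.0f s; %d spikes total\n",
    x$n_neurons, x$duration_s, sum(lengths(x$spikes))
  ))
  invisible(x)
}

#' @method tidy spike_train_set
#' @export
tidy.spike_train_set <- function(x, ...) {
  tibble(
    neuron = rep.int(seq_len(x$n_neurons), lengths(x$spikes)),
    time_s = unlist(x$spikes, use.names = FALSE) %||% numeric(0)
  )
}
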