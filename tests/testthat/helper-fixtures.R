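# Shared fixtures, built in code at test time.

# A compact simulation: few subjects/blocks, reduced sampling rate, white
# noise, no between-subject variability unless asked for. Fast enough for
# unit tests while exercising the full code path.
tiny_config <- function(seed = 1, n_subjects = 4, n_blocks = 2, n_trials = 60,
                        sample_rate = 128, noise_sd = 2, subject_sd = 0,
                        latency_jitter_sd = 0, components = NULL, ...) {
  simulation_config(
    n_subjects = n_subjects, n_blocks = n_blocks, n_trials = n_trials,
    sample_rate = sample_rate, noise_sd = noise_sd, subject_sd = subject_sd,
    latency_jitter_sd = latency_jitter_sd,
    noise_model = "white", noise_band = NULL,
    components = components, seed = seed, ...
  )
}

# A single deterministic component: negative wave at 200 ms on Cz.
one_component <- function(decay = decay_spec(1, a = 0.1, b = 0.9),
                          latency = 0.2, amplitude = 5, width = 0.03,
                          polarity = -1) {
  list(component_spec("N2", c(Cz = 1, C3 = 0.5, C4 = 0.5), latency,
                      width = width, polarity = polarity,
                      base_amplitude = amplitude, decay = decay))
}

# Build a trial_series directly from a samples x trials matrix (one channel).
series_from_matrix <- function(m, times = NULL, channel = "Cz",
                               subject_id = "s01") {
  if (is.null(times)) times <- epoch_times(nrow(m), c(0, 1))
  data <- array(0, c(ncol(m), 1, nrow(m)))
  data[, 1, ] <- t(m)
  structure(list(data = data, times = times, channels = channel,
                 subject_id = subject_id, modality = "Abeta", n_blocks = 1L),
            class = "trial_series")
}

# Simulate + preprocess one group into per-subject trial series.
simulate_series <- function(cfg, reject_uv = NULL) {
  lapply(seq_len(cfg$n_subjects), function(i) {
    preprocess_subject(erphab:::simulate_subject(cfg, i)$blocks,
                       reject_uv = reject_uv, n_trials = cfg$n_trials)
  })
}

# Exact one-sample signed-rank reference: enumerate all 2^n sign assignments
# of the observed magnitudes and convert the upper-tail probability of the
# observed W+ into a normal quantile.
exact_signed_rank_z <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_upper <- (sum(w_all > w_obs) + 0.5 * sum(w_all == w_obs)) / length(w_all)
  stats::qnorm(1 - p_upper)
}

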