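#' Specify one ERP component for simulation
#'
#' A component is a smooth unimodal deflection (Gaussian-windowed pulse) with a
#' scalp topography, a peak latency, a temporal width, a polarity and a base
#' amplitude, plus an attached [decay_spec()] describing how its amplitude
#' changes across the 60 trials of a block.
#'
#' @param name label, conventionally one of "N1", "N2", "P2", "P4".
#' @param topography named numeric vector mapping channel label -> gain
#'   (unitless; channels absent from the map get gain 0). Lateralised
#'   topographies are specified for right-hand stimulation; left-hand blocks
#'   mirror them across the midline.
#' @param latency peak latency in seconds relative to stimulus onset; must lie
#'   inside the epoch window.
#' @param width temporal spread (Gaussian SD) in seconds; > 0.
#' @param polarity +1 or -1.
#' @param base_amplitude peak amplitude in microvolts (positive; the sign is
#'   carried by `polarity`).
#' @param decay a [decay_spec()]; amplitude multiplier per trial.
#' @return object of class `component_spec`.
#' @export
component_spec <- function(name, topography, latency, width, polarity = -1,
                           base_amplitude = 1, decay = decay_spec(4, c = 1)) {
  if (!is.numeric(topography) || is.null(names(topography))) {
    stop_erphab("topography must be a named numeric vector (channel -> gain)")
  }
  assert_finite(topography, "topography gains")
  if (!(is.finite(width) && width > 0)) stop_erphab("width must be > 0")
  if (!(latency > -0.2 && latency < 0.8)) {
    stop_erphab("latency ", latency, " s outside (-0.2, 0.8)")
  }
  if (!polarity %in% c(-1, 1)) stop_erphab("polarity must be +1 or -1")
  if (!inherits(decay, "decay_spec")) stop_erphab("decay must be a decay_spec")
  structure(list(name = name, topography = topography, latency = latency,
                 width = width, polarity = polarity,
                 base_amplitude = base_amplitude, decay = decay),
            class = "component_spec")
}

#' Default component sets for the two stimulus modalities
#'
#' Four components per modality: the lateralised somatosensory waves N1 and P4
#' (maximal over the central electrode contralateral to the stimulated hand,
#' i.e. C3 for right-hand stimulation) and the vertex waves N2 and P2 (maximal
#' at Cz). Latencies follow the group peak latencies reported for
#' transcutaneous electrical (Abeta) and laser (Adelta) stimulation: Abeta
#' N1 112 ms, N2 125 ms, P2 225 ms; Adelta N1 181 ms, N2 202 ms, P2 317 ms.
#' P4 latencies (not tabulated for these data) are placed after the P2.
#' All components share a hyperbolic decay `y = 0.1 + 0.9/x`, i.e. trial-1
#' amplitude 1 falling toward an asymptote of 10%.
#'
#' @param modality "Abeta" or "Adelta".
#' @return list of [component_spec()].
#' @export
default_components <- function(modality = c("Abeta", "Adelta")) {
  modality <- match.arg(modality)
  lat <- if (modality == "Abeta") {
    c(N1 = 0.112, N2 = 0.125, P2 = 0.225, P4 = 0.300)
  } else {
    c(N1 = 0.181, N2 = 0.202, P2 = 0.317, P4 = 0.390)
  }
  dec <- function() decay_spec(1, a = 0.1, b = 0.9)
  list(
    component_spec("N1", c(C3 = 1, C4 = 0.1, Cz = 0.3), lat[["N1"]],
                   width = 0.015, polarity = -1, base_amplitude = 4,
                   decay = dec()),
    component_spec("N2", c(Cz = 1, C3 = 0.7, C4 = 0.7, Fz = 0.6), lat[["N2"]],
                   width = 0.025, polarity = -1, base_amplitude = 8,
                   decay = dec()),
    component_spec("P2", c(Cz = 1, C3 = 0.7, C4 = 0.7, Fz = 0.6), lat[["P2"]],
                   width = 0.045, polarity = +1, base_amplitude = 10,
                   decay = dec()),
    component_spec("P4", c(C3 = 1, C4 = 0.1, Cz = 0.3), lat[["P4"]],
                   width = 0.050, polarity = +1, base_amplitude = 3,
                   decay = dec())
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the study design: 16 subjects per modality, 10 blocks of
#' 60 stimuli at 1 Hz, epochs of 1024 samples at 1024 Hz spanning -0.2 to
#' 0.8 s (half-open), right- and left-hand blocks alternating (half the
#' subjects start with a right-hand block). Background noise defaults to an
#' AR(1) process (coefficient 0.95 at 1024 Hz, a correlation time of about
#' 20 ms) scaled to 10 uV marginal SD, approximating bandpass-filtered EEG
#' background; the noise is spatially correlated across channels
#' (`channel_correlation`), as common-reference EEG background is, so bipolar
#' derivations cancel most of it. Between-subject variability mimics real
#' group ERP data in two ways: every subject scales each component's
#' amplitude by an independent lognormal factor with unit mean
#' (`subject_sd`) and shifts each component's latency by an independent
#' normal offset (`latency_jitter_sd`), both fixed within subject.
#'
#' @param n_subjects,n_blocks,n_trials design counts.
#' @param sample_rate sampling rate in Hz.
#' @param epoch_window epoch span in seconds, `c(start, end)`, half-open.
#' @param channels channel labels simulated.
#' @param components list of [component_spec()].
#' @param subject_sd SD of the log amplitude factors, drawn independently per
#'   subject and component (0.5 is roughly a +/- 65% amplitude spread).
#' @param latency_jitter_sd SD (seconds) of the per-subject, per-component
#'   latency offsets.
#' @param noise_sd marginal SD of the additive noise, microvolts per sample.
#' @param noise_model "ar1" or "white".
#' @param ar1_coefficient AR(1) coefficient in [0, 1).
#' @param channel_correlation correlation of the background noise between any
#'   two channels, in [0, 1).
#' @param noise_band band limits (Hz) applied to the continuous per-block
#'   noise before slicing it into epochs, emulating the band-limited
#'   background of preprocessed EEG; `NULL` disables filtering.
#' @param modality "Abeta" or "Adelta" (metadata; also picks the default
#'   component set when `components` is not given).
#' @param seed master integer seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 16L, n_blocks = 10L, n_trials = 60L,
                              sample_rate = 1024, epoch_window = c(-0.2, 0.8),
                              channels = c("C3", "C4", "Cz", "Fz"),
                              components = NULL,
                              subject_sd = 0.5, latency_jitter_sd = 0.015,
                              noise_sd = 10,
                              noise_model = c("ar1", "white"),
                              ar1_coefficient = 0.95,
                              channel_correlation = 0.9,
                              noise_band = c(0.5, 30),
                              modality = c("Abeta", "Adelta"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  modality <- match.arg(modality)
  if (is.null(components)) components <- default_components(modality)
  stopifnot(n_trials >= 2, n_subjects >= 1, n_blocks >= 1, noise_sd >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            channel_correlation >= 0, channel_correlation < 1,
            latency_jitter_sd >= 0,
            epoch_window[1] < 0, epoch_window[2] > epoch_window[1])
  if (!all(vapply(components, inherits, TRUE, "component_spec"))) {
    stop_erphab("components must all be component_spec objects")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 n_trials = as.integer(n_trials),
                 sample_rate = sample_rate, epoch_window = epoch_window,
                 channels = channels, components = components,
                 subject_sd = subject_sd,
                 latency_jitter_sd = latency_jitter_sd, noise_sd = noise_sd,
                 noise_model = noise_model, ar1_coefficient = ar1_coefficient,
                 channel_correlation = channel_correlation,
                 noise_band = noise_band,
                 modality = modality, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Time axis of an epoch
#'
#' Half-open sampling of `epoch_window`: `round(-start * rate)` pre-stimulus
#' samples, `t = 0` exactly on a sample, `round(diff(window) * rate)` samples
#' in total (1024 for the default window at 1024 Hz).
#'
#' @inheritParams simulation_config
#' @return numeric vector of times in seconds.
#' @export
epoch_times <- function(sample_rate = 1024, epoch_window = c(-0.2, 0.8)) {
  n_pre <- round(-epoch_window[1] * sample_rate)
  n_tot <- round(diff(epoch_window) * sample_rate)
  (seq_len(n_tot) - 1 - n_pre) / sample_rate
}

#' Construct an epoched-EEG container
#'
#' @param data numeric array, trials x channels x samples, microvolts.
#' @param times sample times in seconds (strictly increasing, length =
#'   dim(data)[3]).
#' @param channels channel labels (length = dim(data)[2]).
#' @param subject_id,block_id identifiers.
#' @param stimulated_hand "left" or "right".
#' @param modality "Abeta" or "Adelta".
#' @param trial_indices original within-block trial numbers (tracked through
#'   artifact rejection); defaults to 1..n_trials.
#' @return object of class `epoch_array`.
#' @export
epoch_array <- function(data, times, channels, subject_id = "s01",
                        block_id = 1L, stimulated_hand = "right",
                        modality = "Abeta", trial_indices = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            dim(data)[3] == length(times))
  if (any(diff(times) <= 0)) stop_erphab("times must be strictly increasing")
  assert_finite(data, "epoch data")
  if (!stimulated_hand %in% c("left", "right")) {
    stop_erphab("stimulated_hand must be 'left' or 'right'")
  }
  if (is.null(trial_indices)) trial_indices <- seq_len(dim(data)[1])
  stopifnot(length(trial_indices) == dim(data)[1])
  dimnames(data) <- NULL
  structure(list(data = data, times = times, channels = channels,
                 subject_id = subject_id, block_id = as.integer(block_id),
                 stimulated_hand = stimulated_hand, modality = modality,
                 trial_indices = as.integer(trial_indices)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %s block %d (%s hand, %s): %d trials x %d channels x %d samples [%g, %g] s\n",
              x$subject_id, x$block_id, x$stimulated_hand, x$modality,
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

# Mirror a right-hand topography across the midline for left-hand stimulation.
.mirror_topography <- function(topography) {
  nm <- vapply(names(topography), function(ch) homologous_channel(ch), "")
  stats::setNames(as.numeric(topography), nm)
}

#' Build the waveform template of one component
#'
#' A Gaussian pulse of SD `width`, centred on the sample nearest `latency`
#' (so the peak is exactly `polarity * base_amplitude * gain` at that sample)
#' and truncated to zero outside +/- 3 widths. One row per channel; channels
#' absent from the topography get an all-zero row.
#'
#' @param spec a [component_spec()].
#' @param times epoch time axis in seconds (must cover `spec$latency`).
#' @param channels channel labels for the rows of the output.
#' @return matrix channels x samples, microvolts.
#' @export
build_component_template <- function(spec, times, channels) {
  stopifnot(inherits(spec, "component_spec"))
  if (spec$latency < times[1] || spec$latency > times[length(times)]) {
    stop_erphab("component latency ", spec$latency,
                " s outside the epoch window")
  }
  centre <- times[which.min(abs(times - spec$latency))]
  pulse <- exp(-0.5 * ((times - centre) / spec$width)^2)
  pulse[abs(times - centre) > 3 * spec$width] <- 0
  gains <- spec$topography[channels]
  gains[is.na(gains)] <- 0
  out <- outer(as.numeric(gains), spec$polarity * spec$base_amplitude * pulse)
  rownames(out) <- channels
  out
}

# Background noise for one block: trials x channels x samples. Emulates
# *pre-processed* EEG background: a continuous AR(1) (or white) process per
# channel spanning the whole block, bandpass-filtered to the analysis band
# (`band`, zero-phase Butterworth) and sliced into contiguous epochs (at 1 Hz
# stimulation the -0.2..0.8 s epochs tile the block exactly). Spatial
# correlation is imposed by mixing a common source into every channel:
#   noise_ch = sqrt(cc) * common + sqrt(1 - cc) * idiosyncratic
# giving each channel marginal SD `sd` and pairwise correlation `cc`.
.simulate_noise_block <- function(n_tr, n_ch, n_s, sd, model, rho, cc,
                                  band, rate) {
  if (sd == 0) return(array(0, c(n_tr, n_ch, n_s)))
  n_long <- n_tr * n_s
  gen <- function(n_series) {
    if (model == "white" || rho == 0) {
      x <- matrix(stats::rnorm(n_long * n_series, sd = sd), n_long, n_series)
    } else {
      innov_sd <- sd * sqrt(1 - rho^2)
      e <- matrix(stats::rnorm(n_long * n_series, sd = innov_sd),
                  n_long, n_series)
      x0 <- stats::rnorm(n_series, sd = sd)
      x <- matrix(as.numeric(
        stats::filter(e, filter = rho, method = "recursive",
                      init = matrix(x0, nrow = 1))), n_long, n_series)
    }
    if (!is.null(band)) {
      x <- t(bandpass_filter(t(x), band[1], band[2], rate))
      # restore the requested marginal SD after band limiting
      x <- x * (sd / stats::sd(as.numeric(x)))
    }
    x
  }
  idio <- gen(n_ch)                                # (trials*samples) x ch
  if (cc > 0) {
    idio <- sqrt(1 - cc) * idio + sqrt(cc) * as.numeric(gen(1L))
  }
  aperm(array(idio, c(n_s, n_tr, n_ch)), c(2, 3, 1))
}

# One subject's blocks; seeded independently per subject so datasets are
# reproducible subject-by-subject (streaming pipelines need not materialise
# the whole group). Subject-level latent variables: one lognormal amplitude
# multiplier and one normal latency offset per component, shared by all
# blocks and trials of that subject.
simulate_subject <- function(config, subject_index) {
  times <- epoch_times(config$sample_rate, config$epoch_window)
  n_s <- length(times)
  n_ch <- length(config$channels)
  n_tr <- config$n_trials
  n_cmp <- length(config$components)
  seed_i <- child_seed(config$seed, 1L, subject_index)
  with_seed(seed_i, {
    mult <- if (config$subject_sd > 0) {
      stats::rlnorm(n_cmp, meanlog = -config$subject_sd^2 / 2,
                    sdlog = config$subject_sd)
    } else rep(1, n_cmp)
    lat_shift <- stats::rnorm(n_cmp, sd = config$latency_jitter_sd)
    curves <- vapply(config$components,
                     function(cs) decay_curve(cs$decay, n_tr), numeric(n_tr))
    # right/left blocks alternate; half the subjects start left
    first_hand <- if (subject_index %% 2 == 1) "right" else "left"
    hands <- rep(c(first_hand, setdiff(c("left", "right"), first_hand)),
                 length.out = config$n_blocks)
    shifted <- function(cs, ci) {
      cs$latency <- min(max(cs$latency + lat_shift[ci],
                            config$epoch_window[1] + 3 * cs$width),
                        config$epoch_window[2] - 3 * cs$width)
      cs
    }
    tmpl <- list(
      right = lapply(seq_len(n_cmp), function(ci) {
        build_component_template(shifted(config$components[[ci]], ci),
                                 times, config$channels)
      }),
      left = lapply(seq_len(n_cmp), function(ci) {
        cs <- shifted(config$components[[ci]], ci)
        cs$topography <- .mirror_topography(cs$topography)
        build_component_template(cs, times, config$channels)
      })
    )
    sig_for <- function(hand) {
      s <- array(0, c(n_tr, n_ch, n_s))
      for (ci in seq_len(n_cmp)) {
        s <- s + outer(mult[ci] * curves[, ci], tmpl[[hand]][[ci]])
      }
      s
    }
    sig_hand <- list(right = sig_for("right"), left = sig_for("left"))
    blocks <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      signal <- sig_hand[[hands[b]]] +
        .simulate_noise_block(n_tr, n_ch, n_s, config$noise_sd,
                              config$noise_model, config$ar1_coefficient,
                              config$channel_correlation,
                              config$noise_band, config$sample_rate)
      blocks[[b]] <- epoch_array(signal, times, config$channels,
                                 subject_id = sprintf("s%02d", subject_index),
                                 block_id = b, stimulated_hand = hands[b],
                                 modality = config$modality)
    }
    list(blocks = blocks, multipliers = mult, latency_shifts = lat_shift,
         curves = curves, hands = hands)
  })
}

#' Simulate a multi-subject epoched EEG dataset with known ground truth
#'
#' Trial `t` of every block is the sum over components of
#' `template * decay_curve[t] * subject_multiplier`, plus additive noise.
#' The same seed reproduces the dataset exactly.
#'
#' @param config a [simulation_config()].
#' @return list with `epochs` (list of [epoch_array()], subjects x blocks) and
#'   `ground_truth` (per-component true decay curves, the subjects x
#'   components amplitude-multiplier and latency-shift matrices, per-subject
#'   block hand sequences, the seed and the config).
#' @export
simulate_group_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config, i))
  epochs <- do.call(c, lapply(subjects, `[[`, "blocks"))
  curves <- subjects[[1]]$curves
  cmp_names <- vapply(config$components, `[[`, "", "name")
  colnames(curves) <- cmp_names
  mults <- do.call(rbind, lapply(subjects, `[[`, "multipliers"))
  shifts <- do.call(rbind, lapply(subjects, `[[`, "latency_shifts"))
  colnames(mults) <- colnames(shifts) <- cmp_names
  gt <- list(
    decay_curves = curves,
    subject_multipliers = mults,
    subject_latency_shifts = shifts,
    block_hands = lapply(subjects, `[[`, "hands"),
    seed = config$seed,
    config = config
  )
  list(epochs = epochs, ground_truth = gt)
}
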