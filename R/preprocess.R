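# Homologous 10-20 pairs across the medio-lateral axis (the montage used for
# recording). Matching is case-insensitive ("Cp3" and "CP3" both work).
.homologous_pairs <- c(
  FP1 = "FP2", F7 = "F8", F3 = "F4", T3 = "T4", C3 = "C4", T5 = "T6",
  P3 = "P4", O1 = "O2", FC3 = "FC4", CP3 = "CP4"
)

# Homologue of one channel label (its own label for midline channels ending
# in "z"); errors on channels with no known homologue.
homologous_channel <- function(channel) {
  up <- toupper(channel)
  if (grepl("Z$", up)) return(channel)
  map <- c(.homologous_pairs, stats::setNames(names(.homologous_pairs),
                                              .homologous_pairs))
  hom <- if (up %in% names(map)) map[[up]] else NULL
  if (is.null(hom)) {
    stop_erphab("channel '", channel,
                "' has no medio-lateral homologue and is not midline")
  }
  # preserve the case style of the input label
  if (channel == tolower(channel)) tolower(hom)
  else if (substr(channel, 2, nchar(channel)) ==
           tolower(substr(channel, 2, nchar(channel)))) {
    paste0(substr(hom, 1, 1), tolower(substr(hom, 2, nchar(hom))))
  } else hom
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order (by default) Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), so the net phase response is zero and peak
#' latencies are preserved. The default band 0.5–30 Hz removes slow drift and
#' line/muscle noise while keeping ERP components intact.
#'
#' @param x numeric matrix channels x samples (a vector is treated as one
#'   channel).
#' @param low,high band edges in Hz, `0 < low < high < rate/2`.
#' @param rate sampling rate in Hz.
#' @param order filter order of the bandpass (must be even; the underlying
#'   lowpass/highpass prototype has order/2).
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(x, low = 0.5, high = 30, rate = 1024, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  assert_finite(x, "signal")
  stopifnot(low > 0, low < high, high < rate / 2, order %% 2 == 0)
  bf <- signal::butter(order / 2, c(low, high) / (rate / 2), type = "pass")
  out <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  if (vec) out[1, ] else out
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' @param continuous numeric matrix channels x samples.
#' @param events stimulus onset positions (1-based sample indices).
#' @param window epoch span in seconds relative to each event,
#'   `c(start, end)`, half-open.
#' @param rate sampling rate in Hz.
#' @param channels channel labels.
#' @param ... metadata passed to [epoch_array()] (subject_id, block_id,
#'   stimulated_hand, modality).
#' @return an [epoch_array()]; events too close to the recording edge are
#'   dropped with a warning.
#' @export
segment_epochs <- function(continuous, events, window = c(-0.2, 0.8),
                           rate = 1024, channels = NULL, ...) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, nrow = 1)
  if (is.null(channels)) {
    channels <- rownames(continuous) %||% paste0("ch", seq_len(nrow(continuous)))
  }
  times <- epoch_times(rate, window)
  n_pre <- sum(times < 0)
  n_tot <- length(times)
  n_samples <- ncol(continuous)
  ok <- events - n_pre >= 1 & events + (n_tot - n_pre - 1) <= n_samples
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge were dropped",
            call. = FALSE)
  }
  events <- events[ok]
  if (length(events) == 0) stop_erphab("no events fit inside the recording")
  data <- array(0, c(length(events), nrow(continuous), n_tot))
  for (i in seq_along(events)) {
    idx <- events[i] + seq.int(-n_pre, n_tot - n_pre - 1)
    data[i, , ] <- continuous[, idx, drop = FALSE]
  }
  epoch_array(data, times, channels, trial_indices = which(ok), ...)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus reference
#' interval.
#'
#' @param epochs an [epoch_array()].
#' @param interval reference interval in seconds, default `c(-0.2, 0)`
#'   (inclusive).
#' @return baseline-corrected [epoch_array()].
#' @export
baseline_correct <- function(epochs, interval = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "epoch_array"))
  sel <- epochs$times >= interval[1] & epochs$times <= interval[2]
  if (!any(sel)) stop_erphab("baseline interval contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples
  epochs
}

#' Remove trials contaminated by large artifacts
#'
#' Automatic peak-to-peak criterion: a trial is removed when its peak-to-peak
#' amplitude on any channel exceeds `threshold`. A warning is raised when 10%
#' or more of the trials are removed (more than expected from a clean
#' recording); removing every trial is an error.
#'
#' @param epochs an [epoch_array()].
#' @param threshold microvolts, > 0 (default 100).
#' @return the cleaned [epoch_array()] with attribute `"rejected"` holding the
#'   removed trial indices (original within-block numbering).
#' @export
reject_artifact_trials <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_array"), threshold > 0)
  p2p <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  bad <- which(apply(p2p, 1, max) > threshold)
  n <- dim(epochs$data)[1]
  if (length(bad) == n) {
    stop_erphab("artifact rejection removed all ", n, " trials (threshold ",
                threshold, " uV)")
  }
  frac <- length(bad) / n
  if (frac >= 0.1) {
    warning(sprintf("artifact rejection removed %.1f%% of trials (>= 10%%)",
                    100 * frac), call. = FALSE)
  }
  rejected <- epochs$trial_indices[bad]
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$trial_indices <- epochs$trial_indices[-bad]
  }
  attr(epochs, "rejected") <- rejected
  attr(epochs, "fraction_rejected") <- frac
  epochs
}

#' Flip lateral channels for left-hand stimulation blocks
#'
#' Swaps homologous 10-20 electrode pairs (Fp1/Fp2, F7/F8, F3/F4, T3/T4,
#' C3/C4, T5/T6, P3/P4, O1/O2, FC3/FC4, CP3/CP4) across the medio-lateral
#' axis for blocks recorded during left-hand stimulation; midline channels
#' and right-hand blocks are unchanged. After flipping, the central electrode
#' contralateral to the stimulated hand (Cc) is C3 for every block, so blocks
#' can be averaged without cancelling lateralised activity.
#'
#' @param epochs an [epoch_array()] with `stimulated_hand` metadata.
#' @return the flipped [epoch_array()].
#' @export
flip_lateral_channels <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  if (epochs$stimulated_hand == "right") return(epochs)
  perm <- match(vapply(epochs$channels, homologous_channel, ""),
                epochs$channels)
  if (anyNA(perm)) {
    stop_erphab("homologue of channel '",
                epochs$channels[which(is.na(perm))[1]],
                "' is not present in the montage")
  }
  epochs$data <- epochs$data[, perm, , drop = FALSE]
  epochs
}

#' Bipolar derivation (anode minus cathode)
#'
#' Used for the lateralised somatosensory waves, measured at the contralateral
#' central electrode referenced to Fz (Cc-Fz).
#'
#' @param epochs an [epoch_array()].
#' @param anode,cathode channel labels, both present in the montage.
#' @return a single-channel [epoch_array()] labelled `"anode-cathode"`.
#' @export
bipolar_derivation <- function(epochs, anode, cathode) {
  stopifnot(inherits(epochs, "epoch_array"))
  ia <- match(anode, epochs$channels)
  ic <- match(cathode, epochs$channels)
  if (is.na(ia)) stop_erphab("channel '", anode, "' not present")
  if (is.na(ic)) stop_erphab("channel '", cathode, "' not present")
  d <- epochs$data[, ia, , drop = FALSE] - epochs$data[, ic, , drop = FALSE]
  epochs$data <- d
  epochs$channels <- paste0(anode, "-", cathode)
  epochs
}

#' Average each trial index across a subject's blocks
#'
#' Element `t` of the result is the mean over blocks of trial `t`; trials
#' removed by artifact rejection are excluded from the mean (the trial is
#' averaged over the remaining blocks). Produces the per-subject series of 60
#' across-block-averaged ERP waveforms, one per trial index.
#'
#' @param blocks list of [epoch_array()] for one subject (shared times and
#'   channels).
#' @param n_trials number of trial indices expected per block (default: the
#'   largest trial index present).
#' @return object of class `trial_series`: `data` (trials x channels x
#'   samples), `times`, `channels`, `subject_id`, `modality`.
#' @export
average_blocks_to_trial_series <- function(blocks, n_trials = NULL) {
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, TRUE, "epoch_array")))
  times <- blocks[[1]]$times
  channels <- blocks[[1]]$channels
  for (b in blocks) {
    if (!isTRUE(all.equal(b$times, times)) ||
        !identical(b$channels, channels)) {
      stop_erphab("blocks differ in time axis or channels")
    }
  }
  if (is.null(n_trials)) {
    n_trials <- max(vapply(blocks, function(b) max(b$trial_indices), 0L))
  }
  acc <- array(0, c(n_trials, length(channels), length(times)))
  cnt <- integer(n_trials)
  for (b in blocks) {
    for (i in seq_along(b$trial_indices)) {
      t <- b$trial_indices[i]
      acc[t, , ] <- acc[t, , ] + b$data[i, , ]
      cnt[t] <- cnt[t] + 1L
    }
  }
  if (any(cnt == 0)) {
    stop_erphab("trial ", which(cnt == 0)[1],
                " is missing from every block after rejection")
  }
  acc <- acc / as.vector(cnt)
  structure(list(data = acc, times = times, channels = channels,
                 subject_id = blocks[[1]]$subject_id,
                 modality = blocks[[1]]$modality,
                 n_blocks = length(blocks)),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("<trial_series> %s (%s): %d trials x %d channels x %d samples, averaged over %d block(s)\n",
              x$subject_id, x$modality, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], x$n_blocks))
  invisible(x)
}

#' Derive the non-habituated and habituated condition ERPs
#'
#' The non-habituated ERP is the response to the first stimulus of the blocks
#' (trial 1 of the series); the habituated ERP averages the responses to later
#' stimuli that yield a stable, habituated response (trials 6–60 by default —
#' the main ERP waves decay only minimally after the first few repetitions).
#'
#' @param series a `trial_series` (see [average_blocks_to_trial_series()]).
#' @param habituated_trials trial indices averaged into the habituated ERP
#'   (default `6:60`; all must be present in the series).
#' @return list with elements `non_habituated` and `habituated`, each of class
#'   `condition_erp`: `kind`, `data` (channels x samples), `trials_used`,
#'   `times`, `channels`.
#' @export
derive_condition_erps <- function(series, habituated_trials = 6:60) {
  stopifnot(inherits(series, "trial_series"))
  n <- dim(series$data)[1]
  if (n < max(habituated_trials)) {
    stop_erphab("series has ", n, " trials; habituated window needs ",
                max(habituated_trials))
  }
  mk <- function(kind, trials) {
    d <- series$data[trials, , , drop = FALSE]
    structure(list(kind = kind,
                   data = apply(d, c(2, 3), mean),
                   trials_used = as.integer(trials),
                   times = series$times, channels = series$channels,
                   subject_id = series$subject_id,
                   modality = series$modality),
              class = "condition_erp")
  }
  list(non_habituated = mk("non_habituated", 1L),
       habituated = mk("habituated", habituated_trials))
}

#' Per-subject preprocessing chain
#'
#' Applies, in order: baseline correction, artifact rejection, medio-lateral
#' flipping of left-hand blocks, and across-block trial averaging. (Filtering
#' and epoching are applied upstream when starting from continuous data; data
#' from the synthetic generator or the epoch container are already epoched.)
#'
#' @param blocks list of [epoch_array()] for one subject.
#' @param baseline baseline interval in seconds.
#' @param reject_uv artifact peak-to-peak threshold in microvolts; `NULL`
#'   skips rejection.
#' @inheritParams average_blocks_to_trial_series
#' @return a `trial_series`.
#' @export
preprocess_subject <- function(blocks, baseline = c(-0.2, 0),
                               reject_uv = 100, n_trials = NULL) {
  blocks <- lapply(blocks, function(b) {
    b <- baseline_correct(b, baseline)
    if (!is.null(reject_uv)) b <- reject_artifact_trials(b, reject_uv)
    flip_lateral_channels(b)
  })
  average_blocks_to_trial_series(blocks, n_trials = n_trials)
}
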