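# Extract one subject's samples x trials matrix at a channel ("Cz") or
# bipolar derivation ("C3-Fz").
.channel_matrix <- function(series, channel) {
  stopifnot(inherits(series, "trial_series"))
  parts <- strsplit(channel, "-", fixed = TRUE)[[1]]
  pick <- function(ch) {
    i <- match(ch, series$channels)
    if (is.na(i)) stop_erphab("channel '", ch, "' not present")
    t(series$data[, i, ])                 # samples x trials
  }
  if (length(parts) == 2) pick(parts[1]) - pick(parts[2]) else pick(channel)
}

#' Build the group-average trial-by-time matrix
#'
#' Column `t` of `M` (samples x trials) is the group mean over subjects of the
#' trial-`t` ERP waveform at the requested channel (e.g. `"Cz"`, nose
#' reference) or bipolar derivation (e.g. `"C3-Fz"`, the contralateral central
#' electrode referenced to Fz).
#'
#' @param series_list list of `trial_series`, one per subject (shared time
#'   axes and trial counts).
#' @param channel channel label, or `"anode-cathode"` for a derivation.
#' @return object of class `group_matrix`: `M`, `times`, `channel`,
#'   `modality`, `n_subjects`.
#' @export
build_group_matrix <- function(series_list, channel) {
  stopifnot(length(series_list) >= 1)
  times <- series_list[[1]]$times
  for (s in series_list) {
    if (!isTRUE(all.equal(s$times, times))) {
      stop_erphab("subjects differ in time axis")
    }
  }
  mats <- lapply(series_list, .channel_matrix, channel = channel)
  M <- Reduce(`+`, mats) / length(mats)
  structure(list(M = M, times = times, channel = channel,
                 modality = series_list[[1]]$modality,
                 n_subjects = length(series_list)),
            class = "group_matrix")
}

#' Singular value decomposition of the group matrix
#'
#' Computes `M = U diag(sigma) V^T`. Columns of `U` (left-singular vectors,
#' length = samples) are the wave components: how the EEG amplitude is
#' modulated across the epoch. Rows of `Vt` (right-singular vectors, length =
#' trials) are the habituation components: how the amplitude is modulated
#' across trials. The rank-1 pair is the optimal least-squares rank-1
#' approximation of `M`, and so on for higher ranks.
#'
#' Sign convention: the SVD sign ambiguity is resolved by flipping each
#' component pair so that its right-singular vector has nonnegative mean over
#' trials — a decaying amplitude series is then positive and its fitted
#' asymptote meaningful.
#'
#' @param gm a [build_group_matrix()] result, or a plain numeric matrix
#'   (samples x trials).
#' @return object of class `svd_result`: `u` (samples x r), `d` (singular
#'   values, descending), `vt` (r x trials), `sign_flips` (logical per rank),
#'   plus `times`/`channel` metadata when available.
#' @export
decompose_group_matrix <- function(gm) {
  M <- if (inherits(gm, "group_matrix")) gm$M else as.matrix(gm)
  assert_finite(M, "group matrix")
  sv <- svd(M)
  flips <- colMeans(sv$v) < 0
  sv$u[, flips] <- -sv$u[, flips]
  sv$v[, flips] <- -sv$v[, flips]
  structure(list(u = sv$u, d = sv$d, vt = t(sv$v), sign_flips = flips,
                 times = if (inherits(gm, "group_matrix")) gm$times,
                 channel = if (inherits(gm, "group_matrix")) gm$channel),
            class = "svd_result")
}

#' Leave-one-out residual noise traces
#'
#' For each subject `i`, the noise trace is the difference between that
#' subject's trial-by-time matrix and the group average computed after
#' excluding subject `i`: `eta_i = y_i - Y_(-i)`. The SVD of these residual
#' traces provides the noise reference against which the signal SVD is
#' tested.
#'
#' @inheritParams build_group_matrix
#' @return list of numeric matrices (samples x trials), one per subject.
#' @export
estimate_loo_noise <- function(series_list, channel) {
  n <- length(series_list)
  if (n < 2) stop_erphab("leave-one-out noise needs >= 2 subjects")
  mats <- lapply(series_list, .channel_matrix, channel = channel)
  total <- Reduce(`+`, mats)
  lapply(seq_len(n), function(i) mats[[i]] - (total - mats[[i]]) / (n - 1))
}

#' Group statistics of the noise SVD
#'
#' Performs an SVD of each subject's residual noise trace, sign-aligns every
#' noise singular vector to the corresponding signal singular vector (positive
#' inner product — without alignment, averaging sign-ambiguous vectors across
#' subjects is ill-defined), scales the per-subject results by `1/sqrt(n)` (a
#' group average of n independent noise realisations has `sqrt(n)`-fold
#' smaller amplitude than a single subject's), and returns the across-subject
#' mean and SEM of the singular values and of every singular-vector element.
#'
#' @param noise_matrices list of residual matrices from [estimate_loo_noise()].
#' @param signal_svd the [decompose_group_matrix()] result of the signal
#'   matrix, used as the alignment reference.
#' @return object of class `noise_svd_stats` with `sigma_mean`, `sigma_sem`
#'   (length = ranks), `u_mean`, `u_sem` (samples x ranks), `v_mean`, `v_sem`
#'   (ranks x trials), `n_subjects`.
#' @export
noise_svd_statistics <- function(noise_matrices, signal_svd) {
  n <- length(noise_matrices)
  if (n < 2) stop_erphab("need >= 2 noise matrices")
  stopifnot(inherits(signal_svd, "svd_result"))
  r <- length(signal_svd$d)
  sig_arr <- matrix(0, n, r)
  u_arr <- array(0, c(dim(signal_svd$u), n))
  v_arr <- array(0, c(dim(signal_svd$vt), n))
  for (i in seq_len(n)) {
    sv <- svd(noise_matrices[[i]])
    for (k in seq_len(r)) {
      if (sum(sv$u[, k] * signal_svd$u[, k]) < 0) sv$u[, k] <- -sv$u[, k]
      if (sum(sv$v[, k] * signal_svd$vt[k, ]) < 0) sv$v[, k] <- -sv$v[, k]
    }
    sig_arr[i, ] <- sv$d / sqrt(n)
    u_arr[, , i] <- sv$u[, seq_len(r)] / sqrt(n)
    v_arr[, , i] <- t(sv$v[, seq_len(r)]) / sqrt(n)
  }
  sem <- function(x) stats::sd(x) / sqrt(n)
  structure(list(
    sigma_mean = colMeans(sig_arr),
    sigma_sem = apply(sig_arr, 2, sem),
    u_mean = apply(u_arr, c(1, 2), mean),
    u_sem = apply(u_arr, c(1, 2), sem),
    v_mean = apply(v_arr, c(1, 2), mean),
    v_sem = apply(v_arr, c(1, 2), sem),
    n_subjects = n
  ), class = "noise_svd_stats")
}

#' Which ranks carry signal above the noise reference?
#'
#' Rank `k` is significant when its singular value exceeds the noise mean plus
#' 2.33 standard errors — a one-tailed test at p = 0.01.
#'
#' @param svd_res a [decompose_group_matrix()] result.
#' @param noise_stats a [noise_svd_statistics()] result.
#' @return logical vector, one entry per rank.
#' @export
significant_ranks <- function(svd_res, noise_stats) {
  stopifnot(inherits(svd_res, "svd_result"),
            inherits(noise_stats, "noise_svd_stats"))
  r <- min(length(svd_res$d), length(noise_stats$sigma_mean))
  svd_res$d[seq_len(r)] >
    noise_stats$sigma_mean[seq_len(r)] + 2.33 * noise_stats$sigma_sem[seq_len(r)]
}

#' Which singular-vector elements differ from the noise reference?
#'
#' An element is significant when it falls outside the band
#' `noise mean +/- 2.58 SEM` — a two-tailed test at p = 0.01. Applied to both
#' the left- (wave) and right- (habituation) singular vectors.
#'
#' @inheritParams significant_ranks
#' @return list with logical matrices `u` (samples x ranks) and `v`
#'   (ranks x trials).
#' @export
significant_vector_elements <- function(svd_res, noise_stats) {
  stopifnot(inherits(svd_res, "svd_result"),
            inherits(noise_stats, "noise_svd_stats"))
  ru <- seq_len(min(ncol(svd_res$u), ncol(noise_stats$u_mean)))
  rv <- seq_len(min(nrow(svd_res$vt), nrow(noise_stats$v_mean)))
  list(
    u = abs(svd_res$u[, ru, drop = FALSE] -
              noise_stats$u_mean[, ru, drop = FALSE]) >
      2.58 * noise_stats$u_sem[, ru, drop = FALSE],
    v = abs(svd_res$vt[rv, , drop = FALSE] -
              noise_stats$v_mean[rv, , drop = FALSE]) >
      2.58 * noise_stats$v_sem[rv, , drop = FALSE]
  )
}

#' Peak latencies of a wave component
#'
#' Finds the local extrema of a left-singular vector restricted to
#' post-stimulus samples flagged significant (or to all post-stimulus samples
#' when no mask is given). Latencies are reported on the sampling grid,
#' relative to stimulus onset, ordered by time; no sub-sample interpolation.
#'
#' @param u numeric left-singular vector (length = samples).
#' @param times epoch time axis in seconds.
#' @param mask optional logical vector: which samples are significant.
#' @return data.frame with columns `latency` (seconds), `polarity` (+1/-1)
#'   and `value`; zero rows when no significant post-stimulus extremum exists.
#' @export
vector_peak_latencies <- function(u, times, mask = NULL) {
  stopifnot(length(u) == length(times))
  if (is.null(mask)) mask <- rep(TRUE, length(u))
  keep <- times > 0 & mask
  s <- length(u)
  is_max <- c(FALSE, u[2:(s - 1)] > u[1:(s - 2)] & u[2:(s - 1)] > u[3:s], FALSE)
  is_min <- c(FALSE, u[2:(s - 1)] < u[1:(s - 2)] & u[2:(s - 1)] < u[3:s], FALSE)
  idx <- which((is_max | is_min) & keep)
  data.frame(latency = times[idx],
             polarity = ifelse(is_max[idx], 1L, -1L),
             value = u[idx])
}

#' @export
print.svd_result <- function(x, ...) {
  cat("<svd_result>", nrow(x$u), "samples x", ncol(x$vt), "trials",
      if (!is.null(x$channel)) paste0("(", x$channel, ")"), "\n")
  cat("  leading singular values:",
      paste(sprintf("%.3g", utils::head(x$d, 5)), collapse = ", "), "...\n")
  invisible(x)
}

#' Diagnostic plot of the SVD habituation decomposition
#'
#' Base-graphics panel: singular-value spectrum with the noise bound, and the
#' wave (left) and habituation (right) components of the first `ranks` ranks
#' with their noise bands.
#'
#' @param svd_res a [decompose_group_matrix()] result (with `times`).
#' @param noise_stats a [noise_svd_statistics()] result.
#' @param ranks which ranks to draw (default 1:2).
#' @return invisible `NULL`; draws on the current device.
#' @export
plot_svd_summary <- function(svd_res, noise_stats, ranks = 1:2) {
  op <- graphics::par(mfrow = c(length(ranks) + 1, 1),
                      mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  r <- seq_along(svd_res$d)
  plot(r, svd_res$d, type = "h", lwd = 2, xlab = "rank",
       ylab = "singular value", main = svd_res$channel %||% "")
  graphics::lines(r, noise_stats$sigma_mean[r] + 2.33 * noise_stats$sigma_sem[r],
                  col = "red")
  tms <- svd_res$times %||% seq_len(nrow(svd_res$u))
  for (k in ranks) {
    plot(tms, svd_res$u[, k], type = "l", xlab = "time (s)",
         ylab = sprintf("u[%d]", k))
    graphics::lines(tms, noise_stats$u_mean[, k] + 2.58 * noise_stats$u_sem[, k],
                    col = "red", lty = 2)
    graphics::lines(tms, noise_stats$u_mean[, k] - 2.58 * noise_stats$u_sem[, k],
                    col = "red", lty = 2)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(NULL)
}

#' Number of leading significant ranks
#'
#' Ranks are retained sequentially from rank 1: the count is the length of
#' the initial run of significant ranks (0 when rank 1 is not significant).
#' Sequential retention is the meaningful summary here because once the
#' retained signal ranks are passed, the rank indices of the observed matrix
#' and of the pure-noise reference are offset by the number of signal ranks,
#' so isolated "significant" ranks deep in the spectrum carry no evidence
#' (see the package vignette).
#'
#' @inheritParams significant_ranks
#' @return integer count.
#' @export
n_significant_ranks <- function(svd_res, noise_stats) {
  sig <- significant_ranks(svd_res, noise_stats)
  if (!length(sig) || !sig[1]) return(0L)
  which.min(c(sig, FALSE)) - 1L
}
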