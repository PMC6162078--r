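#' Configure an end-to-end analysis run
#'
#' @param simulation a [simulation_config()] describing synthetic input, or
#'   `NULL` when `input` is given.
#' @param input path to an HDF5 epoch container (see [read_dataset()]), or
#'   `NULL` to simulate.
#' @param channels named character vector of channels/derivations to analyse
#'   (default: the vertex channel `Cz` against the nose reference in the
#'   recording, and the contralateral central electrode against Fz,
#'   `C3-Fz`).
#' @param critical_z cluster-forming threshold for the cluster test.
#' @param n_perm permutations for the cluster test.
#' @param cluster_statistic `"max"` or `"mean"`, see [permutation_reference()].
#' @param max_ranks how many SVD ranks to model.
#' @param n_iterations shuffle-resampling iterations for the decay fits.
#' @param baseline baseline-correction interval (seconds).
#' @param reject_uv artifact rejection threshold (microvolts), `NULL` to skip.
#' @param habituated_trials trials averaged into the habituated ERP.
#' @param seed master seed; all stage seeds derive from it, so a rerun with
#'   the same config reproduces every number exactly.
#' @param out_dir optional output directory for CSV tables and diagnostic
#'   plots.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(), input = NULL,
                       channels = c(vertex = "Cz", lateral = "C3-Fz"),
                       critical_z = 1.96, n_perm = 1000L,
                       cluster_statistic = "max",
                       max_ranks = 3L, n_iterations = 1000L,
                       baseline = c(-0.2, 0), reject_uv = 100,
                       habituated_trials = 6:60,
                       seed = 1L, out_dir = NULL) {
  if (is.null(input) && is.null(simulation)) {
    stop_erphab("either a simulation config or an input path is required")
  }
  structure(list(simulation = simulation, input = input, channels = channels,
                 critical_z = critical_z, n_perm = as.integer(n_perm),
                 cluster_statistic = cluster_statistic,
                 max_ranks = as.integer(max_ranks),
                 n_iterations = as.integer(n_iterations),
                 baseline = baseline, reject_uv = reject_uv,
                 habituated_trials = habituated_trials,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Subject-wise data acquisition: simulate (streaming, one subject at a time)
# or read the container and group blocks by subject.
.subject_series <- function(config) {
  n_trials <- NULL
  if (!is.null(config$input)) {
    epochs <- read_dataset(config$input)
    ids <- vapply(epochs, `[[`, "", "subject_id")
    groups <- split(epochs, ids)
  } else {
    sim <- config$simulation
    n_trials <- sim$n_trials
    groups <- lapply(seq_len(sim$n_subjects), function(i) {
      simulate_subject(sim, i)$blocks
    })
    names(groups) <- sprintf("s%02d", seq_along(groups))
  }
  lapply(groups, function(blocks) {
    preprocess_subject(blocks, baseline = config$baseline,
                       reject_uv = config$reject_uv, n_trials = n_trials)
  })
}

# Condition ERP waveforms as a subjects x samples matrix for one channel.
.condition_matrix <- function(series_list, channel, which_cond,
                              habituated_trials) {
  rows <- lapply(series_list, function(s) {
    conds <- derive_condition_erps(s, habituated_trials)
    erp <- conds[[which_cond]]
    m <- .channel_matrix(
      structure(list(data = array(erp$data, c(1, dim(erp$data))),
                     times = erp$times, channels = erp$channels),
                class = "trial_series"),
      channel)
    as.numeric(m)
  })
  do.call(rbind, rows)
}

#' Run the full habituation analysis
#'
#' Executes, per channel of interest: derivation of the non-habituated
#' (trial 1) and habituated (trials 6–60) condition ERPs with a one-sample
#' cluster-level permutation test of each against baseline (post-stimulus
#' window); the SVD of the group trial-by-time matrix with the leave-one-out
#' noise-SVD significance procedure; peak latencies of the significant wave
#' components; and decay-model selection with shuffle-resampling inference on
#' the habituation components of the first `max_ranks` ranks.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `clusters`,
#'   `singular_values`, `peak_latencies`, `decay_fits` (data.frames), `svd`
#'   (per-channel raw objects), `config` and `seed`. When `config$out_dir` is
#'   set the tables are also written as CSV files plus a diagnostic plot per
#'   channel.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  series_list <- .subject_series(config)
  times <- series_list[[1]]$times
  post <- times >= 0

  clusters <- list(); sv_rows <- list(); peak_rows <- list(); fit_rows <- list()
  svd_store <- list()
  ch_idx <- 0L
  for (nm in names(config$channels)) {
    ch <- config$channels[[nm]]
    ch_idx <- ch_idx + 1L

    for (cond in c("non_habituated", "habituated")) {
      vals <- .condition_matrix(series_list, ch, cond,
                                config$habituated_trials)
      ct <- cluster_test(vals[, post, drop = FALSE], times = times[post],
                         critical_z = config$critical_z,
                         n_perm = config$n_perm,
                         seed = child_seed(config$seed, 2L, ch_idx),
                         statistic = config$cluster_statistic)
      if (nrow(ct)) {
        ct$channel <- nm; ct$condition <- cond
        clusters[[length(clusters) + 1L]] <- ct
      }
    }

    gm <- build_group_matrix(series_list, ch)
    dec <- decompose_group_matrix(gm)
    noise <- noise_svd_statistics(estimate_loo_noise(series_list, ch), dec)
    sig_rank <- significant_ranks(dec, noise)
    sig_elem <- significant_vector_elements(dec, noise)
    svd_store[[nm]] <- list(group_matrix = gm, svd = dec, noise = noise,
                            significant_ranks = sig_rank,
                            significant_elements = sig_elem)

    r <- seq_along(dec$d)
    sv_rows[[nm]] <- data.frame(
      channel = nm, rank = r, sigma = dec$d,
      noise_mean = noise$sigma_mean[r], noise_sem = noise$sigma_sem[r],
      noise_bound = noise$sigma_mean[r] + 2.33 * noise$sigma_sem[r],
      significant = sig_rank[r])

    for (k in seq_len(min(config$max_ranks, length(dec$d)))) {
      pk <- vector_peak_latencies(dec$u[, k], times, sig_elem$u[, k])
      if (nrow(pk) == 0) pk <- vector_peak_latencies(dec$u[, k], times)
      if (nrow(pk)) {
        pk$channel <- nm; pk$rank <- k
        peak_rows[[length(peak_rows) + 1L]] <- pk
      }
      cmp <- decay_model_comparison(
        dec$vt[k, ], n_iterations = config$n_iterations,
        seed = child_seed(config$seed, 3L, ch_idx * 100L + k))
      for (m in 1:4) {
        f <- cmp$fits[[m]]
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          channel = nm, rank = k, model = m,
          a = f$params["a"] %||% NA_real_,
          b = f$params["b"] %||% NA_real_,
          c = f$params["c"] %||% NA_real_,
          rss = f$rss, bic = f$bic,
          winner = m == cmp$winner,
          habituation_detected = cmp$habituation_detected,
          p_resample = cmp$p_resample, row.names = NULL)
      }
    }
  }

  report <- structure(list(
    clusters = if (length(clusters)) do.call(rbind, clusters)
               else data.frame(),
    singular_values = do.call(rbind, c(sv_rows, list(make.row.names = FALSE))),
    peak_latencies = if (length(peak_rows)) do.call(rbind, peak_rows)
                     else data.frame(),
    decay_fits = do.call(rbind, fit_rows),
    svd = svd_store,
    config = config, seed = config$seed,
    version = as.character(utils::packageVersion("erphab"))
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report to CSV tables (plus diagnostic plots)
#'
#' @param report a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(report$clusters, "clusters.csv")
  wr(report$singular_values, "singular_values.csv")
  wr(report$peak_latencies, "peak_latencies.csv")
  wr(report$decay_fits, "decay_fits.csv")
  meta <- list(seed = report$seed, version = report$version,
               channels = as.list(report$config$channels),
               n_perm = report$config$n_perm,
               n_iterations = report$config$n_iterations,
               critical_z = report$config$critical_z,
               max_ranks = report$config$max_ranks)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "run_meta.json"))
  for (nm in names(report$svd)) {
    grDevices::png(file.path(dir, paste0("svd_", nm, ".png")),
                   width = 800, height = 900)
    plot_svd_summary(report$svd[[nm]]$svd, report$svd[[nm]]$noise)
    grDevices::dev.off()
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  for (nm in names(x$svd)) {
    sig <- x$svd[[nm]]$significant_ranks
    nseq <- if (!sig[1]) 0L else which.min(c(sig, FALSE)) - 1L
    cat(sprintf("  %s: %d leading significant rank(s)\n", nm, nseq))
  }
  nsig <- if (nrow(x$clusters)) sum(x$clusters$significant) else 0
  cat("  significant clusters:", nsig, "\n")
  w <- unique(x$decay_fits[x$decay_fits$winner & x$decay_fits$rank == 1,
                           c("channel", "model", "p_resample")])
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  %s rank-1 winning model: %d (p = %.4g)\n",
                w$channel[i], w$model[i], w$p_resample[i]))
  }
  invisible(x)
}
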