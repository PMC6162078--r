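# Signed-rank decomposition used by both the observed test and the
# permutation loop. For a one-sample Wilcoxon signed-rank test, W+ - E[W+]
# equals half the sum of sign(x_i) * rank(|x_i|) over the nonzero values, and
# |x| (hence the ranks, the zero set and the tie-corrected variance) is
# invariant under sign flips — so a whole-waveform sign-flip permutation only
# changes the signs, and the full permutation null can be computed with one
# matrix product.
.signed_rank_parts <- function(values) {
  n <- nrow(values)
  p <- ncol(values)
  sr <- matrix(0, n, p)
  sdv <- numeric(p)
  for (j in seq_len(p)) {
    x <- values[, j]
    nz <- which(x != 0)
    m <- length(nz)
    if (m == 0L) next
    r <- rank(abs(x[nz]))
    sr[nz, j] <- sign(x[nz]) * r
    tie <- table(r)
    v <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie^3 - tie) / 48
    sdv[j] <- sqrt(v)
  }
  list(sr = sr, sd = sdv)
}

#' Point-by-point one-sample Wilcoxon signed-rank z-scores
#'
#' For every sample (time point), tests the subjects' values against zero with
#' the Wilcoxon signed-rank statistic under its normal approximation: zeros
#' are discarded, ties are mid-ranked with the variance correction, and no
#' continuity correction is applied. The sign of z matches the direction of
#' the deflection.
#'
#' @param values numeric matrix, subjects x samples.
#' @param times optional time axis (seconds) carried through to the result.
#' @return object of class `pointwise_z`: list with `z` (length = samples),
#'   `times`, `n_subjects`.
#' @export
pointwise_wilcoxon_z <- function(values, times = NULL) {
  values <- as.matrix(values)
  assert_finite(values, "values")
  parts <- .signed_rank_parts(values)
  z <- ifelse(parts$sd > 0, colSums(parts$sr) / (2 * parts$sd), 0)
  structure(list(z = as.numeric(z), times = times,
                 n_subjects = nrow(values)),
            class = "pointwise_z")
}

.z_vector <- function(z) if (inherits(z, "pointwise_z")) z$z else as.numeric(z)

# Cluster extraction on a plain numeric z vector; returns a data.frame.
.clusters_of <- function(z, critical_z) {
  lab <- integer(length(z))
  lab[z > critical_z] <- 1L
  lab[z < -critical_z] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(), sign = integer(),
                      mass = numeric()))
  }
  starts <- starts[keep]
  ends <- ends[keep]
  data.frame(start = starts, end = ends + 1L, sign = r$values[keep],
             mass = vapply(seq_along(starts),
                           function(i) sum(z[starts[i]:ends[i]]), 0))
}

#' Extract supra-threshold clusters from a pointwise z series
#'
#' Maximal runs of contiguous samples with `z > critical_z` (positive
#' clusters) or `z < -critical_z` (negative clusters). The cluster-level
#' statistic (`mass`) is the sum of the z-scores in the run. Indices are
#' half-open: the cluster covers samples `start` to `end - 1`.
#'
#' @param z a [pointwise_wilcoxon_z()] result or a numeric z vector.
#' @param critical_z cluster-forming threshold, > 0 (default 1.96, two-sided
#'   0.05 under the normal approximation).
#' @return data.frame with columns `start`, `end` (half-open sample indices),
#'   `sign`, `mass`, and `t_start`/`t_end` in seconds when a time axis is
#'   available.
#' @export
extract_clusters <- function(z, critical_z = 1.96) {
  stopifnot(critical_z > 0)
  times <- if (inherits(z, "pointwise_z")) z$times
  cl <- .clusters_of(.z_vector(z), critical_z)
  if (!is.null(times) && nrow(cl)) {
    cl$t_start <- times[cl$start]
    cl$t_end <- times[pmin(cl$end, length(times))]
  }
  cl
}

#' Permutation reference distribution of cluster magnitude
#'
#' Under the one-sample null hypothesis (no consistent deflection), each
#' subject's whole waveform is exchangeable with its sign-flipped copy. Each
#' iteration independently flips the sign of every subject's waveform with
#' probability 1/2, recomputes the pointwise z-series, extracts clusters, and
#' records a per-iteration cluster magnitude summary:
#'
#' * `"max"` (default): the maximum of |cluster mass| (0 if no clusters) —
#'   the max-statistic reference that controls the family-wise error rate;
#' * `"mean"`: the mean of |cluster mass| over that iteration's clusters —
#'   a per-iteration average magnitude reference.
#'
#' @inheritParams pointwise_wilcoxon_z
#' @param critical_z cluster-forming threshold.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed (same seed, same distribution).
#' @param statistic `"max"` or `"mean"` (see above).
#' @return numeric vector of length `n_perm` with attributes `statistic`,
#'   `critical_z`, `n_perm`, `seed`.
#' @export
permutation_reference <- function(values, critical_z = 1.96, n_perm = 1000L,
                                  seed = 1L,
                                  statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  if (n_perm < 100L) stop_erphab("n_perm must be >= 100")
  parts <- .signed_rank_parts(values)
  n <- nrow(values)
  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  num <- signs %*% parts$sr              # n_perm x samples, = 2*(W+ - mu)
  den <- 2 * parts$sd
  den[den == 0] <- Inf                   # all-zero samples give z = 0
  ref <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    cl <- .clusters_of(num[i, ] / den, critical_z)
    ref[i] <- if (nrow(cl) == 0) 0 else {
      if (statistic == "max") max(abs(cl$mass)) else mean(abs(cl$mass))
    }
  }
  structure(ref, statistic = statistic, critical_z = critical_z,
            n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Assess cluster significance against a permutation reference
#'
#' A cluster is significant when its |mass| exceeds the 97.5th percentile of
#' the reference distribution (two-sided test at 0.05 via the magnitude). The
#' p-value is the add-one permutation estimator
#' `(1 + #{reference >= |mass|}) / (n_perm + 1)`.
#'
#' @param clusters data.frame from [extract_clusters()].
#' @param reference numeric vector from [permutation_reference()].
#' @return `clusters` with `p_value` and `significant` columns appended.
#' @export
evaluate_cluster_significance <- function(clusters, reference) {
  if (length(reference) == 0) stop_erphab("empty reference distribution")
  thr <- stats::quantile(reference, 0.975, names = FALSE)
  np <- length(reference)
  clusters$p_value <- vapply(clusters$mass, function(m) {
    (1 + sum(reference >= abs(m))) / (np + 1)
  }, 0)
  clusters$significant <- abs(clusters$mass) > thr
  clusters
}

#' One-sample cluster-level permutation test
#'
#' Full chain: pointwise Wilcoxon z-scores, cluster extraction, permutation
#' reference, cluster significance.
#'
#' @inheritParams permutation_reference
#' @param times optional time axis (seconds).
#' @return data.frame of clusters with p-values and significance flags;
#'   attributes `z` (the [pointwise_wilcoxon_z()] result) and `reference`.
#' @export
cluster_test <- function(values, times = NULL, critical_z = 1.96,
                         n_perm = 1000L, seed = 1L,
                         statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  pz <- pointwise_wilcoxon_z(values, times)
  cl <- extract_clusters(pz, critical_z)
  ref <- permutation_reference(values, critical_z, n_perm, seed, statistic)
  cl <- evaluate_cluster_significance(cl, ref)
  attr(cl, "z") <- pz
  attr(cl, "reference") <- ref
  cl
}
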