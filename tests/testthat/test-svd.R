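test_that("decomposition matches known factorizations", {
  d <- decompose_group_matrix(diag(c(2, 1)))
  expect_equal(d$d, c(2, 1))

  u <- c(3, 4) / 5
  v <- c(1, 2, 2) / 3
  m <- 5 * outer(u, v)
  d2 <- decompose_group_matrix(m)
  expect_equal(d2$d[1], 5)
  expect_lt(max(abs(d2$d[-1])), 1e-10)
  recon1 <- d2$d[1] * outer(d2$u[, 1], d2$vt[1, ])
  expect_equal(recon1, m, tolerance = 1e-12)
  expect_error(decompose_group_matrix(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("reconstruction and Eckart-Young identities hold numerically", {
  m <- withr::with_seed(1, matrix(rnorm(40), 8, 5))
  d <- decompose_group_matrix(m)
  recon <- d$u %*% diag(d$d) %*% d$vt
  expect_lt(norm(m - recon, "F") / norm(m, "F"), 1e-10)
  # orthonormality
  expect_equal(crossprod(d$u), diag(5), tolerance = 1e-12)
  expect_equal(tcrossprod(d$vt), diag(5), tolerance = 1e-12)
  # rank-2 truncation error equals the l2 norm of the dropped singular values
  m2 <- d$u[, 1:2] %*% diag(d$d[1:2]) %*% d$vt[1:2, ]
  expect_equal(norm(m - m2, "F"), sqrt(sum(d$d[3:5]^2)), tolerance = 1e-10)
})

test_that("sign convention makes every habituation component nonnegative-mean", {
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(rnorm(60 * 20), 60, 20))
    d <- decompose_group_matrix(m)
    expect_true(all(rowMeans(d$vt) >= 0))
    recon <- d$u %*% diag(d$d) %*% d$vt
    expect_lt(norm(m - recon, "F") / norm(m, "F"), 1e-8)
  }
})

test_that("leave-one-out noise traces follow the displayed formula", {
  mk <- function(m) series_from_matrix(m)
  A <- matrix(1, 4, 3); B <- matrix(2, 4, 3); C <- matrix(7, 4, 3)
  eta <- estimate_loo_noise(list(mk(A), mk(B), mk(C)), "Cz")
  expect_equal(eta[[1]], A - (B + C) / 2)
  expect_equal(eta[[2]], B - (A + C) / 2)
  expect_equal(eta[[3]], C - (A + B) / 2)

  # identical subjects leave no residual
  eta2 <- estimate_loo_noise(list(mk(A), mk(A)), "Cz")
  expect_true(all(eta2[[1]] == 0))
  expect_error(estimate_loo_noise(list(mk(A)), "Cz"), ">= 2")

  # the weighted residuals always sum to zero by construction
  mats <- withr::with_seed(2, lapply(1:6, function(i) matrix(rnorm(12), 4, 3)))
  eta3 <- estimate_loo_noise(lapply(mats, mk), "Cz")
  expect_lt(max(abs(Reduce(`+`, eta3))), 1e-10)
})

test_that("noise SVD statistics: scaling, degenerate SEM, sign-flip invariance", {
  m <- withr::with_seed(3, matrix(rnorm(60), 10, 6))
  ref <- decompose_group_matrix(m)
  stats4 <- noise_svd_statistics(list(m, m, m, m), ref)
  expect_equal(stats4$sigma_mean, svd(m)$d / sqrt(4))
  expect_true(all(stats4$sigma_sem == 0))
  expect_true(all(stats4$u_sem == 0))

  noise <- withr::with_seed(4, lapply(1:4, function(i) matrix(rnorm(60), 10, 6)))
  s1 <- noise_svd_statistics(noise, ref)
  flipped <- noise; flipped[[2]] <- -flipped[[2]]
  s2 <- noise_svd_statistics(flipped, ref)
  expect_equal(s1$sigma_mean, s2$sigma_mean)
  expect_equal(s1$u_mean, s2$u_mean, tolerance = 1e-12)
  expect_equal(s1$v_mean, s2$v_mean, tolerance = 1e-12)
})

test_that("rank significance applies the one-tailed 2.33 SE rule strictly", {
  m <- withr::with_seed(5, matrix(rnorm(60), 10, 6))
  dec <- decompose_group_matrix(m)
  noise <- noise_svd_statistics(list(m, m), dec)
  # sigma equals the reference mean when n = 2 identical matrices scaled back
  fake <- dec; fake$d <- noise$sigma_mean
  expect_false(any(significant_ranks(fake, noise)))
  fake$d <- rep(0, length(fake$d))
  expect_false(any(significant_ranks(fake, noise)))
  fake$d <- noise$sigma_mean + 1
  expect_true(all(significant_ranks(fake, noise)))   # SEM = 0 here
  expect_identical(n_significant_ranks(fake, noise), length(fake$d))
})

test_that("vector-element significance is the two-tailed 2.58 SEM band", {
  m <- withr::with_seed(6, matrix(rnorm(60), 10, 6))
  dec <- decompose_group_matrix(m)
  noise <- noise_svd_statistics(list(m, m), dec)   # SEM = 0, mean = svd(m)/sqrt(2)
  sig <- significant_vector_elements(dec, noise)
  # elements equal to the noise mean are not significant, all others are
  expect_identical(sig$u, abs(dec$u - noise$u_mean) > 0)
  expect_identical(sig$v, abs(dec$vt - noise$v_mean) > 0)
})

test_that("peak latencies report post-stimulus extrema on the sampling grid", {
  times <- epoch_times(256)
  u <- exp(-0.5 * ((times - 0.2) / 0.02)^2)
  pk <- vector_peak_latencies(u, times)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$latency - 0.2), 1 / 256 + 1e-12)
  expect_identical(pk$polarity, 1L)

  biph <- -exp(-0.5 * ((times - 0.12) / 0.02)^2) +
    exp(-0.5 * ((times - 0.25) / 0.04)^2)
  pk2 <- vector_peak_latencies(biph, times)
  expect_identical(pk2$polarity, c(-1L, 1L))
  expect_true(all(diff(pk2$latency) > 0))

  expect_equal(nrow(vector_peak_latencies(u, times, rep(FALSE, length(u)))), 0)
  # pre-stimulus extrema are excluded
  pre <- exp(-0.5 * ((times + 0.1) / 0.02)^2)
  expect_equal(nrow(vector_peak_latencies(pre, times)), 0)
})

test_that("group matrix averages subjects at the requested channel or derivation", {
  m1 <- matrix(1:12, 4, 3); m2 <- matrix(12:1, 4, 3)
  gm <- build_group_matrix(list(series_from_matrix(m1), series_from_matrix(m2)),
                           "Cz")
  expect_equal(gm$M, (m1 + m2) / 2)

  gm1 <- build_group_matrix(list(series_from_matrix(m1)), "Cz")
  expect_equal(gm1$M, m1)

  # opposite waveforms cancel
  gm0 <- build_group_matrix(list(series_from_matrix(m1), series_from_matrix(-m1)),
                            "Cz")
  expect_true(all(gm0$M == 0))

  cfg <- tiny_config(seed = 7, n_subjects = 2, noise_sd = 0)
  ser <- simulate_series(cfg)
  gmd <- build_group_matrix(ser, "C3-Fz")
  gc3 <- build_group_matrix(ser, "C3")
  gfz <- build_group_matrix(ser, "Fz")
  expect_equal(gmd$M, gc3$M - gfz$M, tolerance = 1e-12)
  expect_error(build_group_matrix(ser, "Oz"), "Oz")
})

test_that("rank-1 habituation is recovered from moderately noisy group data", {
  dec_true <- decay_spec(1, a = 0.1, b = 0.9)
  curve <- decay_curve(dec_true, 60)
  hits <- vapply(1:10, function(s) {
    cfg <- tiny_config(seed = s, n_subjects = 8, n_blocks = 2, noise_sd = 1.5,
                       sample_rate = 256,
                       components = one_component(dec_true))
    ser <- simulate_series(cfg)
    d <- decompose_group_matrix(build_group_matrix(ser, "Cz"))
    cor(d$vt[1, ], curve) > 0.95
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
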