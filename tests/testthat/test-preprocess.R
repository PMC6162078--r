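test_that("bandpass keeps the passband and rejects DC and high frequencies", {
  rate <- 1024
  t <- seq(0, 16, by = 1 / rate)
  mid <- seq(4 * rate, 12 * rate)   # away from filter edge transients

  s10 <- sin(2 * pi * 10 * t)
  g10 <- max(abs(bandpass_filter(s10, 0.5, 30, rate)[mid]))
  expect_gt(g10, 0.95)
  expect_lt(g10, 1.05)

  s100 <- sin(2 * pi * 100 * t)
  expect_lt(max(abs(bandpass_filter(s100, 0.5, 30, rate)[mid])), 0.05)

  dc <- rep(5, length(t))
  expect_lt(max(abs(bandpass_filter(dc, 0.5, 30, rate)[mid])), 0.05)

  expect_error(bandpass_filter(c(1, NA, 3), 0.5, 30, rate), "non-finite")
})

test_that("epoch segmentation aligns t = 0 to the event sample", {
  rate <- 1024
  cont <- matrix(0, 1, 65 * rate)
  events <- (1:60) * rate
  cont[1, events] <- 7   # impulse at each stimulus onset
  ep <- segment_epochs(cont, events, rate = rate, channels = "Cz")
  expect_equal(dim(ep$data), c(60, 1, 1024))
  i0 <- which(ep$times == 0)
  expect_true(all(ep$data[, 1, i0] == 7))

  expect_warning(
    ep2 <- segment_epochs(cont, c(10L, events), rate = rate, channels = "Cz"),
    "dropped")
  expect_equal(dim(ep2$data)[1], 60)
})

test_that("baseline correction zeroes the reference interval and is shift-invariant", {
  times <- epoch_times(128)
  ep <- epoch_array(array(5, c(3, 2, length(times))), times, c("Cz", "Fz"))
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data)), 0)

  # purely post-stimulus content is untouched
  tm <- build_component_template(one_component()[[1]], times, c("Cz", "Fz"))
  ep2 <- epoch_array(aperm(array(tm, c(2, length(times), 3)), c(3, 1, 2)),
                     times, c("Cz", "Fz"))
  expect_equal(baseline_correct(ep2)$data, ep2$data, tolerance = 1e-12)

  ep3 <- ep2; ep3$data <- ep3$data + 3.7
  expect_equal(baseline_correct(ep3)$data, baseline_correct(ep2)$data,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-0.5, -0.4)), "no samples")
})

test_that("artifact rejection removes exactly the contaminated trials", {
  cfg <- tiny_config(seed = 2, n_subjects = 1, n_blocks = 1, noise_sd = 2)
  ep <- erphab:::simulate_subject(cfg, 1)$blocks[[1]]
  clean <- reject_artifact_trials(ep, 200)
  expect_length(attr(clean, "rejected"), 0)

  spiked <- ep
  spiked$data[7, 2, 100] <- 500
  out <- expect_silent(reject_artifact_trials(spiked, 200))
  expect_identical(attr(out, "rejected"), 7L)
  expect_equal(dim(out$data)[1], 59)
  expect_identical(out$trial_indices, setdiff(1:60, 7L))

  expect_error(reject_artifact_trials(spiked, 1e-6), "all 60 trials")
  med_p2p <- stats::median(apply(spiked$data, 1,
                                 function(m) max(m) - min(m)))
  expect_warning(reject_artifact_trials(spiked, med_p2p), ">= 10%")
})

test_that("medio-lateral flipping swaps homologous pairs only for left-hand blocks", {
  times <- epoch_times(128)
  chans <- c("C3", "C4", "Cz", "Fz")
  data <- array(0, c(2, 4, length(times)))
  data[, 2, ] <- 1   # signal only on C4
  right <- epoch_array(data, times, chans, stimulated_hand = "right")
  expect_identical(flip_lateral_channels(right)$data, data)

  left <- epoch_array(data, times, chans, stimulated_hand = "left")
  fl <- flip_lateral_channels(left)
  expect_true(all(fl$data[, 1, ] == 1))   # moved to C3
  expect_true(all(fl$data[, 2, ] == 0))
  expect_identical(flip_lateral_channels(fl)$data, data)  # involution

  bad <- epoch_array(data, times, c("C3", "C4", "Cz", "XX"),
                     stimulated_hand = "left")
  expect_error(flip_lateral_channels(bad), "XX")
})

test_that("bipolar derivation subtracts the reference channel", {
  times <- epoch_times(128)
  x <- sin(2 * pi * 5 * times)
  data <- array(0, c(2, 3, length(times)))
  data[1, 1, ] <- x; data[2, 1, ] <- 2 * x
  ep <- epoch_array(data, times, c("C3", "Fz", "Cz"))
  d <- bipolar_derivation(ep, "C3", "Fz")
  expect_equal(d$channels, "C3-Fz")
  expect_equal(d$data[1, 1, ], x)

  same <- bipolar_derivation(ep, "C3", "C3")
  expect_true(all(same$data == 0))
  neg <- bipolar_derivation(ep, "Fz", "C3")
  expect_equal(neg$data, -d$data)
  expect_error(bipolar_derivation(ep, "C3", "Oz"), "Oz")
})

test_that("trial averaging across blocks honours rejected trials", {
  times <- epoch_times(128)
  mk <- function(val, trials = 1:3) {
    epoch_array(array(val, c(length(trials), 1, length(times))), times, "Cz",
                trial_indices = trials)
  }
  ts1 <- average_blocks_to_trial_series(list(mk(2), mk(2)))
  expect_equal(ts1$data, mk(2)$data)

  ts2 <- average_blocks_to_trial_series(list(mk(1), mk(-1)))
  expect_true(all(ts2$data == 0))

  # block 2 lost trial 2: trial 2 averages over block 1 only
  b1 <- mk(4); b2 <- mk(8, trials = c(1L, 3L))
  ts3 <- average_blocks_to_trial_series(list(b1, b2), n_trials = 3)
  expect_equal(ts3$data[1, 1, 1], 6)
  expect_equal(ts3$data[2, 1, 1], 4)
  expect_equal(ts3$data[3, 1, 1], 6)

  expect_error(
    average_blocks_to_trial_series(list(mk(1, 1:2), mk(1, 1:2)), n_trials = 3),
    "trial 3")
})

test_that("condition ERPs use trial 1 and trials 6-60", {
  m <- matrix(3, nrow = 16, ncol = 60)   # constant over trials
  ser <- series_from_matrix(m)
  conds <- derive_condition_erps(ser)
  expect_identical(conds$non_habituated$trials_used, 1L)
  expect_identical(conds$habituated$trials_used, 6:60)
  expect_equal(unname(conds$non_habituated$data[1, ]), rep(3, 16))
  expect_equal(unname(conds$habituated$data[1, ]), rep(3, 16))

  # decaying series: habituated amplitude equals the mean decay over 6..60
  curve <- decay_curve(decay_spec(1, a = 0.1, b = 0.9), 60)
  m2 <- outer(rep(1, 16), curve)
  conds2 <- derive_condition_erps(series_from_matrix(m2))
  expect_equal(unname(conds2$habituated$data[1, 1]), mean(curve[6:60]),
               tolerance = 1e-12)

  short <- series_from_matrix(matrix(1, 16, 30))
  expect_error(derive_condition_erps(short), "60")
})

test_that("zero-noise pipeline reproduces template times decay at every trial", {
  dec <- decay_spec(1, a = 0.1, b = 0.9)
  cfg <- tiny_config(seed = 3, n_subjects = 2, noise_sd = 0,
                     components = one_component(dec))
  ser <- simulate_series(cfg)
  times <- ser[[1]]$times
  tm <- build_component_template(cfg$components[[1]], times,
                                 c("C3", "C4", "Cz", "Fz"))
  curve <- decay_curve(dec, 60)
  for (t in c(1, 2, 30, 60)) {
    expect_equal(ser[[1]]$data[t, , ], curve[t] * tm, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
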