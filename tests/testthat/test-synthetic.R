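test_that("component templates peak exactly at the nearest sample", {
  times <- epoch_times(1024)
  spec <- component_spec("N2", c(Cz = 1), 0.125, width = 0.02, polarity = -1,
                        base_amplitude = 1)
  tm <- build_component_template(spec, times, c("Cz", "Fz"))
  i <- which.min(abs(times - 0.125))
  expect_equal(min(tm["Cz", ]), -1)
  expect_equal(unname(which.min(tm["Cz", ])), i)
  # gain defaults to zero for unlisted channels
  expect_true(all(tm["Fz", ] == 0))
  # zero outside +/- 3 widths
  expect_true(all(tm["Cz", abs(times - 0.125) > 3 * 0.02] == 0))
})

test_that("templates superpose linearly", {
  times <- epoch_times(256)
  a <- component_spec("N2", c(Cz = 1), 0.125, 0.025, -1, 8)
  b <- component_spec("P2", c(Cz = 1), 0.225, 0.045, +1, 10)
  both <- build_component_template(a, times, "Cz") +
    build_component_template(b, times, "Cz")
  expect_equal(both,
               build_component_template(a, times, "Cz") +
                 build_component_template(b, times, "Cz"))
  expect_error(
    build_component_template(
      component_spec("X", c(Cz = 1), 0.79, 0.02), epoch_times(256, c(-0.2, 0.5)),
      "Cz"),
    "outside")
})

test_that("epoch time axis is half-open with t = 0 on a sample", {
  tms <- epoch_times(1024, c(-0.2, 0.8))
  expect_length(tms, 1024)
  expect_true(0 %in% tms)
  expect_equal(diff(range(tms)), 1023 / 1024)
  expect_equal(unique(round(diff(tms), 10)), 1 / 1024)
})

test_that("deterministic simulation: same seed identical, new seed different", {
  cfg1 <- tiny_config(seed = 5, n_subjects = 2, noise_sd = 3)
  d1 <- simulate_group_dataset(cfg1)
  d2 <- simulate_group_dataset(tiny_config(seed = 5, n_subjects = 2, noise_sd = 3))
  expect_identical(d1$epochs, d2$epochs)
  expect_identical(d1$ground_truth$decay_curves, d2$ground_truth$decay_curves)
  d3 <- simulate_group_dataset(tiny_config(seed = 6, n_subjects = 2, noise_sd = 3))
  expect_false(identical(d1$epochs, d3$epochs))
})

test_that("noise-free constant-model data makes every trial identical", {
  cfg <- tiny_config(seed = 1, n_subjects = 2, noise_sd = 0,
                     components = one_component(decay_spec(4, c = 0.7)))
  sim <- simulate_group_dataset(cfg)
  ep <- sim$epochs[[1]]
  tm <- build_component_template(cfg$components[[1]], ep$times, ep$channels)
  for (t in c(1, 17, 60)) {
    expect_equal(ep$data[t, , ], 0.7 * tm, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("noise-free hyperbolic decay scales trials as (a+b)/(a+b/2)", {
  cfg <- tiny_config(seed = 1, n_subjects = 1, noise_sd = 0,
                     components = one_component(decay_spec(1, a = 0.2, b = 0.8)))
  ep <- simulate_group_dataset(cfg)$epochs[[1]]
  peak1 <- max(abs(ep$data[1, 3, ]))   # Cz
  peak2 <- max(abs(ep$data[2, 3, ]))
  expect_equal(peak1 / peak2, (0.2 + 0.8) / (0.2 + 0.8 / 2), tolerance = 1e-12)
})

test_that("a single noise-free component gives a rank-1 matrix along the decay curve", {
  dec <- decay_spec(1, a = 0.1, b = 0.9)
  cfg <- tiny_config(seed = 2, n_subjects = 3, noise_sd = 0,
                     components = one_component(dec))
  ser <- simulate_series(cfg)
  gm <- build_group_matrix(ser, "Cz")
  sv <- svd(gm$M)
  expect_lt(sv$d[2] / sv$d[1], 1e-10)
  curve <- decay_curve(dec, 60)
  expect_equal(abs(cor(sv$v[, 1], curve)), 1, tolerance = 1e-9)
})

test_that("ground truth records the latent subject variables", {
  cfg <- tiny_config(seed = 9, n_subjects = 3, noise_sd = 1, subject_sd = 0.4,
                     latency_jitter_sd = 0.01)
  gt <- simulate_group_dataset(cfg)$ground_truth
  expect_equal(dim(gt$subject_multipliers), c(3, 4))
  expect_equal(dim(gt$subject_latency_shifts), c(3, 4))
  expect_true(all(gt$subject_multipliers > 0))
  expect_equal(colnames(gt$decay_curves), c("N1", "N2", "P2", "P4"))
  # right/left alternation, half the subjects starting left
  expect_identical(gt$block_hands[[1]][1], "right")
  expect_identical(gt$block_hands[[2]][1], "left")
})

test_that("the HDF5 container round-trips exactly", {
  cfg <- tiny_config(seed = 4, n_subjects = 2, n_blocks = 2, noise_sd = 2)
  sim <- simulate_group_dataset(cfg)
  f <- withr::local_tempfile(fileext = ".h5")
  write_dataset(sim, f)
  back <- read_dataset(f)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$data, sim$epochs[[i]]$data)
    expect_identical(back[[i]]$times, sim$epochs[[i]]$times)
    expect_identical(back[[i]]$channels, sim$epochs[[i]]$channels)
    expect_identical(back[[i]]$stimulated_hand, sim$epochs[[i]]$stimulated_hand)
    expect_identical(back[[i]]$trial_indices, sim$epochs[[i]]$trial_indices)
  }
})

test_that("missing container members are reported by name", {
  cfg <- tiny_config(seed = 4, n_subjects = 1, n_blocks = 1, noise_sd = 2)
  sim <- simulate_group_dataset(cfg)
  f <- withr::local_tempfile(fileext = ".h5")
  write_dataset(sim, f)
  rhdf5::h5delete(f, "s01_b01/times")
  expect_error(read_dataset(f), "times")
  expect_error(read_dataset("/nonexistent/file.h5"), "no such file")
})

test_that("an empty dataset writes and reads as an empty container", {
  f <- withr::local_tempfile(fileext = ".h5")
  write_dataset(list(), f)
  expect_length(read_dataset(f), 0)
})
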