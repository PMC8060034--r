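test_that("downsampling 1000 -> 200 Hz keeps 621 samples and preserves DC", {
  n_samp <- 3101
  data <- array(rep(2.5, 2 * 3 * n_samp), dim = c(2, 3, n_samp))
  ep <- toy_epochs(data, fs_hz = 1000,
                   labels = data.frame(direction = c("left", "right"),
                                       deflection_ms = c(1226, 1230)))
  ds <- downsample(ep, 200)
  expect_equal(dim(ds$data)[3], 621)
  expect_equal(ds$time_ms[1], -100)
  expect_equal(ds$time_ms[2] - ds$time_ms[1], 5)
  # constant signal survives the anti-alias filter exactly (unit DC gain)
  expect_equal(max(abs(ds$data - 2.5)), 0, tolerance = 1e-6)
  expect_identical(ds$labels, ep$labels)
})

test_that("downsampling preserves band-limited content and validates factors", {
  t_ms <- seq(-100, 3000, by = 1)
  sine <- sin(2 * pi * 10 * t_ms / 1000)     # 10 Hz, well under 100 Hz Nyquist
  data <- array(0, dim = c(1, 1, length(t_ms)))
  data[1, 1, ] <- sine
  ep <- toy_epochs(data, fs_hz = 1000,
                   labels = data.frame(direction = "left", deflection_ms = 1226))
  ds <- downsample(ep, 200)
  interior <- ds$time_ms > 0 & ds$time_ms < 2900    # away from edge padding
  err <- abs(ds$data[1, 1, interior] - sin(2 * pi * 10 * ds$time_ms[interior] / 1000))
  expect_lt(max(err), 0.02)

  expect_identical(downsample(ep, 1000), ep)     # identity at the same rate
  expect_error(downsample(ep, 300), "integer decimation")
})

test_that("distance binning partitions onset-to-deflection into 15 windows", {
  sub <- small_subject(3, n_blocks = 1, max_trials = 10)
  bn <- bin_distances(sub$epochs)
  expect_equal(bn$n_bins, 15)
  expect_equal(dim(bn$features)[2], 15)
  expect_false(anyNA(bn$features))

  # edges run from 0 to the per-trial deflection with equal widths
  for (i in 1:2) {
    e <- bn$bin_edges_ms[i, ]
    expect_equal(e[1], 0)
    expect_equal(e[16], bn$labels$deflection_ms[i])
    expect_equal(diff(range(diff(e))), 0, tolerance = 1e-9)
    expect_equal(diff(e)[1], bn$labels$deflection_ms[i] / 15)
  }

  # a 1226-ms deflection gives ~81.7-ms windows
  expect_equal(1226 / 15, 81.73, tolerance = 1e-3)
})

test_that("bin membership uses the nearer-object rule on exact boundaries", {
  # deflection 1500 ms at 200 Hz: windows of 100 ms; t = 100 ms sits on the
  # boundary between the first (distance 15) and second (distance 14) window
  n_samp <- 621
  data <- array(0, dim = c(1, 1, n_samp))
  t_ms <- -100 + (seq_len(n_samp) - 1) * 5
  data[1, 1, ] <- t_ms                       # feature values encode time
  ep <- toy_epochs(data, labels = data.frame(direction = "left", deflection_ms = 1500))
  bn <- bin_distances(ep, samples_per_bin = 25)   # keep >= all 20 samples per bin
  b15 <- bn$features[1, 15, ]
  b14 <- bn$features[1, 14, ]
  expect_false(100 %in% b15)   # boundary sample excluded from the farther bin
  expect_true(100 %in% b14)    # ... and assigned to the nearer-object window
  expect_true(all(b15 >= 0 & b15 < 100))
  expect_true(all(b14 >= 100 & b14 < 200))
})

test_that("feature vectors have equal length and sensor-major order", {
  n_samp <- 621
  data <- array(0, dim = c(2, 3, n_samp))
  t_ms <- -100 + (seq_len(n_samp) - 1) * 5
  for (s in 1:3) data[, s, ] <- rep(1000 * s + t_ms, each = 2)
  ep <- toy_epochs(data, labels = data.frame(direction = c("left", "right"),
                                             deflection_ms = c(1216, 1236)))
  bn <- bin_distances(ep, samples_per_bin = 5)
  # trials with different deflections still give identical feature lengths
  expect_equal(dim(bn$features), c(2, 15, 3 * 5))
  # sensor-major flattening: first 5 entries from sensor 1, next 5 sensor 2
  f <- bn$features[1, 15, ]
  expect_true(all(f[1:5] >= 1000 & f[1:5] < 2000))
  expect_true(all(f[6:10] >= 2000 & f[6:10] < 3000))
  expect_true(all(f[11:15] >= 3000))
})

test_that("direction pooling is idempotent and conserves trials", {
  sub <- small_subject(4, n_blocks = 1, max_trials = 30)
  bn <- bin_distances(sub$epochs)
  pooled <- pool_directions(bn)
  expect_true(pooled$pooled)
  expect_equal(dim(pooled$features), dim(bn$features))
  expect_identical(pool_directions(pooled), pooled)
  # direction labels are retained for bookkeeping
  expect_true(all(c("left", "right") %in% pooled$labels$direction))

  one_dir <- subset_binned(bn, bn$labels$direction == "left")
  expect_warning(pool_directions(one_dir), "only one direction")
})

test_that("pooling removes the direction confound from distance decoding", {
  # direction-only signal, no distance information
  sm <- small_sensors(n_sensors = 12, noise_sd = 1, dist_strength = 0,
                      attention_gain = 1)
  sub <- small_subject(6, n_blocks = 1, sensors = sm, max_trials = 60)
  bn <- pool_directions(bin_distances(sub$epochs))
  rdm <- decode_distance_pairwise(bn, n_folds = 5, seed = 8)
  accs <- rdm$matrix[lower.tri(rdm$matrix)]
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("trial-count equalization subsamples to the global minimum", {
  sets <- list(a = 1:30, b = 101:125, c = 201:240)
  eq <- equalize_trial_counts(sets, seed = 5)
  expect_true(all(vapply(eq, length, integer(1)) == 25))
  expect_identical(eq$b, sets$b)                      # already at the minimum
  for (nm in names(sets)) {
    expect_true(all(eq[[nm]] %in% sets[[nm]]))
    expect_false(anyDuplicated(eq[[nm]]) > 0)         # without replacement
  }
  # identical sizes pass through unchanged
  same <- list(x = 1:10, y = 11:20)
  expect_identical(equalize_trial_counts(same, 1), same)
  expect_error(equalize_trial_counts(list(a = 1:3, b = integer(0)), 1), "b")
})

test_that("epoch containers validate their invariants", {
  expect_error(epoch_set(array(0, c(2, 2, 5)), time_ms = c(0, 1, 2, 3, 3.5),
                         fs_hz = 1000, labels = data.frame(x = 1:2)),
               "uniform step")
  expect_error(epoch_set(array(0, c(2, 2, 5)), time_ms = 0:4, fs_hz = 1000,
                         labels = data.frame(deflection_ms = c(2, 99))),
               "deflection")
})
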