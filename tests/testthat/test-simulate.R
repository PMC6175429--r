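test_that("identical seeds reproduce the dataset exactly, including serialization", {
  ds1 <- simulate_dataset(tiny_config(seed = 5, n_trials = 10), tiny_array(12))
  ds2 <- simulate_dataset(tiny_config(seed = 5, n_trials = 10), tiny_array(12))
  expect_identical(ds1[[1]]$epochs$data, ds2[[1]]$epochs$data)
  expect_identical(ds1[[1]]$epochs$labels, ds2[[1]]$epochs$labels)
  expect_identical(ds1[[1]]$epochs$coil_traces, ds2[[1]]$epochs$coil_traces)
  d1 <- tempfile(); d2 <- tempfile()
  write_epochs(ds1[[1]]$epochs, d1); write_epochs(ds2[[1]]$epochs, d2)
  expect_identical(readBin(file.path(d1, "data.bin"), "raw", 1e7),
                   readBin(file.path(d2, "data.bin"), "raw", 1e7))
  ds3 <- simulate_dataset(tiny_config(seed = 6, n_trials = 10), tiny_array(12))
  expect_false(identical(ds1[[1]]$epochs$data, ds3[[1]]$epochs$data))
})

test_that("epoch invariants hold: regular time axis with onset on a sample", {
  e <- tiny_epochs(n_trials = 5)
  expect_equal(length(e$times), dim(e$data)[3])
  expect_equal(diff(e$times), rep(1 / e$sfreq, length(e$times) - 1),
               tolerance = 1e-12)
  expect_true(any(abs(e$times) < 1e-12))
  expect_true(all(e$labels %in% c("angry", "neutral")))
})

test_that("injected effect appears only after onset, on the recorded topography", {
  arr <- tiny_array(16)
  cfg <- tiny_config(amplitude = 3, onset = 100, seed = 2, n_trials = 120,
                     sfreq = 200, window = c(-0.2, 0.4))
  ds <- simulate_dataset(cfg, arr)
  e <- ds[[1]]$epochs
  dif <- apply(e$data[e$labels == "angry", , , drop = FALSE], c(2, 3), mean) -
         apply(e$data[e$labels == "neutral", , , drop = FALSE], c(2, 3), mean)
  pre <- e$times < 0.098
  post <- e$times > 0.15 & e$times < 0.35
  # pre-onset contrast is pure noise; post-onset carries the pattern
  expect_lt(max(abs(colMeans(t(dif[, pre])))), 0.5)
  topo <- ds[[1]]$truth$effect_topographies[[1]]
  proj <- as.vector(t(dif) %*% topo)
  expect_lt(max(abs(proj[pre])), 1)
  expect_gt(mean(proj[post]), 2)
  # amplitude 0: conditions statistically exchangeable (t below Bonferroni)
  ds0 <- simulate_dataset(tiny_config(amplitude = 0, seed = 3, n_trials = 120,
                                      sfreq = 200, window = c(-0.2, 0.4)),
                          arr)
  e0 <- ds0[[1]]$epochs
  ia <- e0$labels == "angry"
  tmax <- max(abs(vapply(seq_len(16), function(ch) {
    vapply(seq(1, length(e0$times), by = 12), function(t)
      t.test(e0$data[ia, ch, t], e0$data[!ia, ch, t])$statistic, numeric(1))
  }, numeric(11))))
  expect_lt(tmax, qt(1 - 0.025 / (16 * 11), df = 100) + 1.5)
})

test_that("noise-free single-component trials are identical within condition", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 4,
    conditions = c("angry", "neutral"), sfreq = 150,
    epoch_window = c(-0.1, 0.3),
    evoked_components = list(list(latency = 100, width = 30, amplitude = 1,
                                  seed = 7)),
    effect_spec = list(),
    noise = list(white_sd = 0, pink_sd = 0, exponent = 1,
                 spatial_scale = 0.04),
    seed = 4)
  ds <- simulate_dataset(cfg, tiny_array(12))
  e <- ds[[1]]$epochs
  expect_equal(e$data[1, , ], e$data[2, , ], tolerance = 1e-12)
  expect_equal(e$data[1, , ], e$data[4, , ], tolerance = 1e-12)
})

test_that("simulated noise follows the configured 1/f exponent over 1-80 Hz", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 20,
    conditions = c("angry", "neutral"), sfreq = 300,
    epoch_window = c(0, 2), evoked_components = list(), effect_spec = list(),
    noise = list(white_sd = 0, pink_sd = 1, exponent = 1, spatial_scale = 0.04),
    seed = 8)
  ds <- simulate_dataset(cfg, tiny_array(12))
  e <- ds[[1]]$epochs
  tp <- length(e$times)
  f <- (seq_len(tp) - 1) * e$sfreq / tp
  psd <- rowMeans(vapply(seq_len(dim(e$data)[1]), function(tr)
    rowMeans(Mod(mvfft(t(e$data[tr, , ])))^2), numeric(tp)))
  keep <- f >= 1 & f <= 80
  slope <- coef(lm(log(psd[keep]) ~ log(f[keep])))[2]
  expect_lt(abs(-slope - 1), 0.2)
})

test_that("dipole simulation has rank-1 structure and errors on radial sources", {
  arr <- tiny_array(24)
  fm <- make_forward_model(arr, grid_resolution = 0.02)
  src <- which.min(rowSums(sweep(fm$grid, 2, c(0.02, 0.02, 0.03))^2))
  tc <- sin(2 * pi * 8 * seq(0, 0.3, by = 1 / 300))
  dp <- simulate_dipole_dataset(fm, src, tc, n_trials = 3, noise_sd = 0,
                                sfreq = 300, seed = 1)
  # outer-product structure: every time slice is proportional to the lead field
  sl <- dp$epochs$data[1, , which.max(abs(tc))]
  expect_gt(abs(cor(sl, dp$truth$leadfield)), 1 - 1e-10)
  expect_equal(dp$truth$source_location, fm$grid[src, ])
  # radial orientation is silent in a spherical conductor
  r0 <- fm$grid[src, ]
  expect_error(simulate_dipole_dataset(fm, src, tc, orientation = r0,
                                       n_trials = 2, sfreq = 300),
               "silent")
  # two uncorrelated dipoles: covariance has exactly two dominant eigenvalues
  src2 <- which.min(rowSums(sweep(fm$grid, 2, c(-0.03, -0.01, 0.02))^2))
  tc2 <- cos(2 * pi * 13 * seq(0, 0.3, by = 1 / 300))
  d1 <- simulate_dipole_dataset(fm, src, tc, n_trials = 4, noise_sd = 1e-4,
                                sfreq = 300, seed = 2)
  d2 <- simulate_dipole_dataset(fm, src2, tc2, n_trials = 4, noise_sd = 1e-4,
                                sfreq = 300, seed = 3)
  e2 <- d1$epochs; e2$data <- d1$epochs$data + d2$epochs$data
  C <- suppressWarnings(compute_covariance(e2, band = NULL))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[2] / ev[3], 100)
})
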