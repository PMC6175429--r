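fm_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_forward_model(tiny_array(24),
                                                 grid_resolution = 0.02)
    val
  }
})

test_that("spherical lead fields silence radial dipoles", {
  fm <- fm_fixture()
  for (i in c(1, nrow(fm$grid) %/% 2, nrow(fm$grid))) {
    r0 <- fm$grid[i, ]
    if (sqrt(sum(r0^2)) < 1e-6) next
    L <- fm$leadfield[i, , ]
    rad <- sqrt(sum((L %*% (r0 / sqrt(sum(r0^2))))^2))
    expect_lt(rad, 1e-10 * sqrt(sum(L^2)))
  }
})

test_that("covariance matches the direct formula and flags rank deficiency", {
  x <- matrix(c(1, 2, 0, -1, 3, 1, 4, 2, 0, 1), 5, 2)
  e <- meg_epochs(array(t(x), c(1, 2, 5)), seq(0, 4) / 100, "a", 100)
  C <- compute_covariance(e, band = NULL)
  expect_equal(unname(C), unname(cov(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # white noise: near-diagonal
  set.seed(1)
  ew <- meg_epochs(array(rnorm(20 * 4 * 500), c(20, 4, 500)),
                   seq(0, 499) / 600, rep("a", 20), 600)
  Cw <- compute_covariance(ew, band = NULL)
  expect_lt(max(abs(Cw[upper.tri(Cw)])), 0.05)
  expect_lt(max(abs(diag(Cw) - 1)), 0.05)
  # rank-1 data warn
  er <- meg_epochs(array(outer(rep(1, 3), outer(c(1, 2, 3), sin(1:50))),
                         c(3, 3, 50)), seq(0, 49) / 100, rep("a", 3), 100)
  expect_warning(Cr <- compute_covariance(er, band = NULL), "rank")
  ev <- eigen(Cr, only.values = TRUE)$values
  expect_gt(ev[1] / max(ev[2], 1e-300), 1e6)
})

test_that("LCMV: unit gain before normalization, localization, depth equalization", {
  fm <- fm_fixture()
  tc <- sin(2 * pi * 11 * seq(0, 0.4, by = 1 / 600))
  src <- which.min(rowSums(sweep(fm$grid, 2, c(0.03, 0.01, 0.03))^2))
  dp <- simulate_dipole_dataset(fm, src, tc, n_trials = 8, noise_sd = 0.05,
                                seed = 2)
  C <- compute_covariance(dp$epochs, band = NULL)
  filt <- lcmv_weights(fm, C)
  # unit gain w'l = 1 exactly (before vector-norm normalization)
  for (i in c(src, 10, 100)) {
    if (!filt$kept[i]) next
    l <- fm$leadfield[i, , ] %*% filt$orientation[i, ]
    w_un <- filt$weights[i, ] * filt$unnormalized_gain[i]
    expect_equal(as.numeric(sum(w_un * l)), 1, tolerance = 1e-8)
  }
  # output power peaks at the simulated source (within one grid step)
  pw <- rowSums((filt$weights %*% C) * filt$weights)
  est <- which.max(pw)
  expect_lte(sqrt(sum((fm$grid[est, ] - fm$grid[src, ])^2)),
             fm$resolution + 1e-9)
  # identity covariance: w proportional to l / ||l||^2, unit gain exact
  Ci <- diag(24)
  fi <- lcmv_weights(fm, Ci, reg = 0)
  i <- src
  l <- as.vector(fm$leadfield[i, , ] %*% fi$orientation[i, ])
  w_expect <- l / sum(l^2)
  w_un <- fi$weights[i, ] * fi$unnormalized_gain[i]
  expect_equal(w_un, w_expect, tolerance = 1e-8)
  # depth bias: white-noise output power varies with depth before
  # normalization, is equalized after
  deep <- which.min(rowSums(fm$grid^2))
  shallow <- which.max(rowSums(fm$grid^2))
  noise_power <- function(w) sum(w^2)          # w' (sigma^2 I) w
  wn_deep <- fi$weights[deep, ] * fi$unnormalized_gain[deep]
  wn_shal <- fi$weights[shallow, ] * fi$unnormalized_gain[shallow]
  ratio_before <- noise_power(wn_deep) / noise_power(wn_shal)
  ratio_after <- noise_power(fi$weights[deep, ]) /
                 noise_power(fi$weights[shallow, ])
  expect_gt(ratio_before, 2)                    # depth bias present
  expect_lt(abs(ratio_after - 1), 0.1)          # equalized within 10%
})

test_that("virtual channels reconstruct sources and vanish on zero data", {
  fm <- fm_fixture()
  tc <- sin(2 * pi * 9 * seq(0, 0.4, by = 1 / 600))
  src <- which.min(rowSums(sweep(fm$grid, 2, c(-0.02, 0.02, 0.04))^2))
  dp <- simulate_dipole_dataset(fm, src, tc, n_trials = 6, noise_sd = 0,
                                seed = 3)
  C0 <- suppressWarnings(compute_covariance(dp$epochs, band = NULL))
  filt <- lcmv_weights(fm, C0)
  vc <- extract_virtual_channels(dp$epochs, filt, sources = src,
                                 normalized = FALSE)
  # unit-gain weights recover the source timecourse up to sign
  expect_gt(abs(cor(vc$data[1, 1, ], tc)), 0.999)
  ez <- dp$epochs; ez$data[] <- 0
  vz <- extract_virtual_channels(ez, filt, sources = src)
  expect_true(all(vz$data == 0))
  # SNR 10, two dipoles: each reconstruction correlates > 0.9 with its source
  src2 <- which.min(rowSums(sweep(fm$grid, 2, c(0.03, -0.03, 0.02))^2))
  tc2 <- cos(2 * pi * 17 * seq(0, 0.4, by = 1 / 600))
  d1 <- simulate_dipole_dataset(fm, src, tc, n_trials = 10, noise_sd = 0.1,
                                seed = 4)
  d2 <- simulate_dipole_dataset(fm, src2, tc2, n_trials = 10, noise_sd = 0,
                                seed = 5)
  e2 <- d1$epochs; e2$data <- d1$epochs$data + d2$epochs$data
  C2 <- compute_covariance(e2, band = NULL)
  f2 <- lcmv_weights(fm, C2)
  v2 <- extract_virtual_channels(e2, f2, sources = c(src, src2))
  m1 <- colMeans(t(sapply(1:10, function(tr) v2$data[tr, 1, ])))
  m2 <- colMeans(t(sapply(1:10, function(tr) v2$data[tr, 2, ])))
  expect_gt(abs(cor(m1, tc)), 0.9)
  expect_gt(abs(cor(m2, tc2)), 0.9)
})

test_that("atlas ROI peaks find active sources; atlas round-trips through NIfTI", {
  fm <- fm_fixture()
  atlas <- make_synthetic_atlas(fm, n_rois = 20, seed = 1)
  expect_equal(length(atlas$labels), nrow(fm$grid))
  expect_equal(length(atlas$names), 20)
  tc <- sin(2 * pi * 12 * seq(0, 0.4, by = 1 / 600))
  src <- 50
  dp <- simulate_dipole_dataset(fm, src, tc, n_trials = 6, noise_sd = 0.02,
                                seed = 6)
  C <- compute_covariance(dp$epochs, band = NULL)
  filt <- lcmv_weights(fm, C)
  vcs <- pick_roi_peaks(dp$epochs, filt, atlas, band = c(1, 100))
  roi_of_src <- atlas$labels[src]
  expect_equal(vcs$peak_index[match(atlas$names[roi_of_src], vcs$roi_names)],
               src)
  vce <- extract_roi_timecourses(dp$epochs, filt, vcs)
  expect_equal(dim(vce$data)[2], length(vcs$roi_names))
  expect_equal(vce$channel_ids, vcs$roi_names)
  # NIfTI + TSV round trip reproduces the labeling on the same grid
  nii <- tempfile(fileext = ".nii.gz"); tsv <- tempfile(fileext = ".tsv")
  write_atlas_nifti(atlas, fm, nii, tsv)
  back <- read_atlas(nii, tsv, fm)
  expect_equal(back$labels, atlas$labels)
  expect_equal(back$names, atlas$names)
})
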