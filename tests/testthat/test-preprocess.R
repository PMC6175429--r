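make_sine_epochs <- function(freqs, sfreq = 600, dur = 4, nch = 2) {
  times <- seq(0, dur, by = 1 / sfreq)
  x <- rowSums(vapply(freqs, function(f) sin(2 * pi * f * times),
                      numeric(length(times))))
  data <- array(rep(x, each = nch), c(1, nch, length(times)))
  meg_epochs(data, times, "stim", sfreq, subject = "T")
}

test_that("comb filter suppresses mains and harmonics below 1% of input", {
  core <- 1000:1400   # interior samples, away from zero-phase edge transients
  e <- make_sine_epochs(50)
  ef <- apply_filter(e, filter_spec("comb", 50))
  expect_lt(max(abs(ef$data[1, 1, core])), 0.01)
  # harmonics too
  e3 <- make_sine_epochs(150)
  ef3 <- apply_filter(e3, filter_spec("comb", 50))
  expect_lt(max(abs(ef3$data[1, 1, core])), 0.01)
  expect_match(ef$meta$filters, "comb")
})

test_that("bandpass removes DC and preserves in-band amplitude within 5%", {
  e <- make_sine_epochs(10, dur = 6)
  e$data <- e$data + 3                      # DC offset
  ef <- apply_filter(e, filter_spec("bandpass", c(0.5, 30)))
  core <- 1500:2100
  expect_lt(abs(mean(ef$data[1, 1, core])), 0.05)
  amp <- (max(ef$data[1, 1, core]) - min(ef$data[1, 1, core])) / 2
  expect_lt(abs(amp - 1), 0.05)
  expect_error(filter_spec("bandpass", c(30, 0.5)))
  expect_error(apply_filter(e, filter_spec("bandpass", c(0.5, 400))),
               "Nyquist")
})

test_that("baseline correction zeroes the baseline window mean exactly", {
  e <- tiny_epochs(n_trials = 4)
  eb <- baseline_correct(e, c(-0.2, 0))
  idx <- which(eb$times >= -0.2 & eb$times <= 0)
  bl <- apply(eb$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-12)
  # constant trial becomes all zeros
  ec <- e; ec$data[] <- 7
  expect_lt(max(abs(baseline_correct(ec, c(-0.2, 0))$data)), 1e-12)
})

test_that("motion rejection removes exactly the trials exceeding 5 mm", {
  e <- tiny_epochs(n_trials = 10)
  # static coils: nothing removed
  e0 <- e; e0$coil_traces[] <- 0
  expect_length(reject_trials(e0, 5)$removed, 0)
  # one trial with a 6 mm jump on one coil
  e1 <- e0; e1$coil_traces[7, 2, 3] <- 6
  r1 <- reject_trials(e1, 5)
  expect_equal(r1$removed, 7L)
  expect_equal(dim(r1$epochs$data)[1], dim(e$data)[1] - 1)
  # random walks: removed set equals a brute-force scan of per-trial maxima
  r <- reject_trials(e, 2)    # low threshold to get some exceedances
  brute <- which(vapply(seq_len(dim(e$coil_traces)[1]), function(tr)
    max(e$coil_traces[tr, , ]), numeric(1)) > 2)
  expect_equal(r$removed, brute)
  # label-blind: permuting labels does not change the removed set
  ep <- e; ep$labels <- sample(ep$labels)
  expect_equal(reject_trials(ep, 2)$removed, brute)
  # missing coil data: pass-through with warning
  en <- e; en$coil_traces <- NULL
  expect_warning(rn <- reject_trials(en, 5), "coil")
  expect_equal(dim(rn$epochs$data), dim(e$data))
})

test_that("subaveraging follows integer division and conserves the grand mean", {
  set.seed(1)
  data <- array(rnorm(33 * 3 * 10), c(33, 3, 10))
  e <- meg_epochs(data, seq(0, 9) / 100, rep("a", 33), 100)
  es <- subaverage(e, 5, seed = 2)
  expect_equal(dim(es$data)[1], 6)          # 33 %/% 5, 3 discarded
  # group_size 1: identity up to order
  e1 <- subaverage(e, 1, seed = 3)
  expect_equal(dim(e1$data)[1], 33)
  expect_equal(sort(e1$data[, 1, 1]), sort(e$data[, 1, 1]))
  # zero remainder: grand mean conserved exactly
  e30 <- meg_epochs(data[1:30, , , drop = FALSE], seq(0, 9) / 100,
                    rep("a", 30), 100)
  es30 <- subaverage(e30, 5, seed = 4)
  expect_equal(apply(es30$data, c(2, 3), mean),
               apply(e30$data, c(2, 3), mean), tolerance = 1e-12)
  # identical trials: pseudo-trial equals any single trial
  ei <- e30; for (i in 1:30) ei$data[i, , ] <- e30$data[1, , ]
  esi <- subaverage(ei, 5, seed = 5)
  expect_equal(esi$data[1, , ], e30$data[1, , ], tolerance = 1e-12)
  # too few trials in a condition: warning, zero pseudo-trials
  es2 <- meg_epochs(data[1:5, , , drop = FALSE], seq(0, 9) / 100,
                    c("a", "a", "a", "b", "b"), 100)
  expect_warning(r <- subaverage(es2, 3, seed = 6), "fewer")
  expect_equal(as.character(unique(r$labels)), "a")
})

test_that("GFP equals the brute-force channel SD of the grand average", {
  e <- tiny_epochs(n_trials = 6)
  v <- compute_evoked(e)
  gfp <- global_field_power(v)
  w <- v$n_trials / sum(v$n_trials)
  ga <- w[1] * v$data[[1]] + w[2] * v$data[[2]]
  brute <- vapply(seq_along(e$times), function(t) sd(ga[, t]), numeric(1))
  expect_equal(gfp, brute, tolerance = 1e-12)
  # half channels +1, half -1 -> GFP about 1 (sd with n-1 denominator)
  vd <- v; vd$data[[1]][] <- rep(c(1, -1), each = 12); vd$data[[2]][] <- vd$data[[1]]
  g1 <- global_field_power(vd)
  expect_equal(unique(round(g1, 6)), round(sd(rep(c(1, -1), each = 12)), 6))
  # identical channels -> GFP 0
  vz <- v; vz$data[[1]][] <- 5; vz$data[[2]][] <- 5
  expect_lt(max(global_field_power(vz)), 1e-12)
  expect_error(compute_evoked(e, "nope"), "unknown")
})

test_that("component windows are found at GFP troughs of a three-bump mixture", {
  times <- seq(0, 0.4, by = 1 / 600)
  tms <- times * 1000
  gfp <- exp(-(tms - 90)^2 / (2 * 15^2)) + 0.8 * exp(-(tms - 150)^2 / (2 * 15^2)) +
         0.9 * exp(-(tms - 250)^2 / (2 * 25^2))
  # analytic troughs of the mixture, found by fine-grid minimization
  fine <- seq(60, 320, by = 0.01)
  mix <- function(t) exp(-(t - 90)^2 / 450) + 0.8 * exp(-(t - 150)^2 / 450) +
    0.9 * exp(-(t - 250)^2 / 1250)
  v <- mix(fine)
  tr <- fine[which(diff(sign(diff(v))) > 0) + 1]
  w <- find_component_windows(gfp, times, search_range = c(60, 320),
                              n_windows = 3, smooth_ms = 5)
  expect_equal(nrow(w), 3)
  bounds <- sort(c(w$t_end[1], w$t_end[2]))
  expect_lt(max(abs(bounds - sort(tr))), 2 * 1000 / 600)  # within ~1 sample
  expect_true(all(w$t_start < w$t_end))
  expect_equal(w$t_start[-1], w$t_end[-3])
  # monotone GFP: no interior minima
  expect_error(find_component_windows(seq_along(times) / 10, times,
                                      c(60, 320), 3), "minima")
  # canonical defaults
  dw <- default_component_windows()
  expect_equal(dw$t_start, c(60, 127, 173))
  expect_equal(dw$t_end, c(127, 173, 317))
})
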