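test_that("permutation p-value follows the conservative (b+1)/(m+1) rule", {
  expect_equal(permutation_pvalue(0, 1000), 1 / 1001)
  expect_equal(permutation_pvalue(49, 999), 0.05)
  expect_equal(permutation_pvalue(19, 19), 1.0)
  # n = 19 permutations give a minimum attainable p of exactly .05
  expect_equal(permutation_pvalue(0, 19), 0.05)
  expect_error(permutation_pvalue(5, 4), "b")
  # floor: never below 1/(m+1)
  for (m in c(1, 10, 999))
    expect_gte(permutation_pvalue(0, m), 1 / (m + 1))
})

test_that("label-shuffle null is calibrated and hits the floor for strong effects", {
  set.seed(1)
  x <- c(rnorm(10, 5), rnorm(10, -5))
  y <- rep(c("a", "b"), each = 10)
  stat <- function(lab) abs(mean(x[lab == "a"]) - mean(x[lab == "b"]))
  pn <- label_shuffle_null(stat, y, n_perm = 99, seed = 2)
  expect_equal(pn$p, 1 / 100)
  # null data: p roughly uniform
  xz <- rnorm(20)
  statz <- function(lab) abs(mean(xz[lab == "a"]) - mean(xz[lab == "b"]))
  ps <- replicate(60, {
    xz <<- rnorm(20)
    label_shuffle_null(statz, y, n_perm = 49)$p
  })
  expect_gt(mean(ps <= 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("max-statistic correction is monotone and costless for duplicated units", {
  set.seed(3)
  null1 <- matrix(rnorm(2000), 1000, 2)
  obs <- c(1.5, 0.2)
  p_corr <- maxstat_correct(obs, null1)
  p_raw <- vapply(1:2, function(j)
    permutation_pvalue(sum(null1[, j] >= obs[j]), 1000), numeric(1))
  expect_true(all(p_corr >= p_raw))
  # single unit: identical to uncorrected
  expect_equal(maxstat_correct(obs[1], null1[, 1]), p_raw[1])
  # perfectly correlated units: correction costless
  nd <- cbind(null1[, 1], null1[, 1])
  pd <- maxstat_correct(c(1.5, 1.5), nd)
  expect_equal(pd[1], pd[2])
  expect_equal(pd[1], permutation_pvalue(sum(null1[, 1] >= 1.5), 1000))
})

test_that("FDR + cluster filtering implements BH step-up and the 5-sample rule", {
  # BH thresholds .0125/.025/.0375/.05 admit all four
  r <- fdr_cluster(c(.01, .02, .03, .04), alpha = .05, min_length = 1)
  expect_true(all(r$sig_mask))
  # 4-sample run removed, 5-sample run kept
  p <- rep(1, 20)
  p[3:6] <- 1e-6                # 4 consecutive
  r4 <- fdr_cluster(p, min_length = 5)
  expect_false(any(r4$sig_mask))
  expect_true(is.na(r4$onset_index))
  p[3:7] <- 1e-6                # 5 consecutive
  r5 <- fdr_cluster(p, min_length = 5)
  expect_equal(which(r5$sig_mask), 3:7)
  expect_equal(r5$onset_index, 3L)
  # all p = 1: empty
  r1 <- fdr_cluster(rep(1, 10))
  expect_false(any(r1$sig_mask))
  # raising alpha never removes a previously significant timepoint
  set.seed(4)
  pv <- runif(50)^2
  m1 <- fdr_cluster(pv, alpha = .05, min_length = 1)$sig_mask
  m2 <- fdr_cluster(pv, alpha = .10, min_length = 1)$sig_mask
  expect_true(all(m2[m1]))
})

test_that("BCa interval reduces to the percentile interval when corrections are off", {
  set.seed(5)
  x <- rnorm(200)
  ci <- bca_ci(x, n_boot = 500, seed = 9, bias_correct = FALSE,
               accelerate = FALSE)
  set.seed(9)
  b <- colMeans(matrix(x[sample.int(200, 200 * 500, replace = TRUE)], 200))
  expect_equal(unname(ci), unname(quantile(b, c(.025, .975), type = 6)))
  # symmetric Gaussian: BCa close to percentile
  ci2 <- bca_ci(x, n_boot = 500, seed = 9)
  w <- diff(ci)
  expect_lt(max(abs(ci2 - ci)), 0.10 * w)
  # degenerate input
  cid <- bca_ci(rep(2, 10))
  expect_equal(unname(cid), c(2, 2), ignore_attr = TRUE)
  expect_true(attr(cid, "degenerate"))
})

test_that("BCa against the boot package oracle on a skewed sample", {
  skip_if_not_installed("boot")
  set.seed(6)
  x <- rexp(40)
  ci <- bca_ci(x, n_boot = 2000, seed = 1)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  bci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  expect_lt(max(abs(ci - bci)), 0.15 * diff(bci))
})

test_that("ERF randomization tests: two-condition F equals squared paired t", {
  set.seed(7)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  rt <- erf_window_tests(x, "paired-t", n_perm = 200, seed = 1)
  rf <- erf_window_tests(x, "rm-anova", n_perm = 200, seed = 1)
  expect_equal(rf$statistic, rt$statistic^2, tolerance = 1e-10)
  # oracle: t.test per sensor
  tor <- vapply(1:5, function(j)
    abs(t.test(x[, j, 1], x[, j, 2], paired = TRUE)$statistic), numeric(1))
  expect_equal(rt$statistic, tor, tolerance = 1e-10)
  # identical conditions -> nothing significant
  xeq <- x; xeq[, , 2] <- xeq[, , 1]
  req <- erf_window_tests(xeq, "paired-t", n_perm = 100, seed = 2)
  expect_true(all(req$p_corrected == 1))
  # one sensor with a large shift -> only that sensor survives correction
  xs <- x; xs[, 3, 1] <- xs[, 3, 1] + 10
  rs <- erf_window_tests(xs, "paired-t", n_perm = 500, seed = 3)
  expect_lt(rs$p_corrected[3], 0.05)
  expect_true(all(rs$p_corrected[-3] > 0.05))
})

test_that("group proportion counts subjects below alpha per unit", {
  p <- rbind(c(rep(.01, 7), rep(.5, 7)), rep(.2, 14), rep(.001, 14))
  gp <- group_proportion(p)
  expect_equal(gp, c(0.5, 0, 1))
})
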