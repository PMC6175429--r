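# Shared permutation/bootstrap machinery: conservative permutation p-values,
# label-shuffle nulls, maximum-statistic FWER control, FDR with temporal
# cluster filtering, BCa bootstrap intervals, ERF randomization tests and
# group proportion maps.

#' Conservative permutation p-value
#'
#' Computes the permutation p-value `(b + 1) / (m + 1)`, where `b` is the
#' number of null statistics greater than or equal to the observed statistic
#' and `m` the number of permutations. This estimator never returns a value
#' below `1/(m + 1)` and treats the observed statistic as one member of the
#' null ensemble.
#'
#' @param b Number of null statistics `>=` the observed one.
#' @param m Number of permutations.
#' @return A probability in `[1/(m+1), 1]`.
#' @examples
#' permutation_pvalue(0, 1000)   # 1/1001
#' permutation_pvalue(49, 999)   # 0.05
#' @export
permutation_pvalue <- function(b, m) {
  stopifnot_scalar(b); stopifnot_scalar(m)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (b < 0 || b > m) stop("'b' must satisfy 0 <= b <= m", call. = FALSE)
  (b + 1) / (m + 1)
}

#' Label-shuffle permutation null for an arbitrary statistic
#'
#' Builds an empirical null by recomputing a statistic after random
#' permutations of the labels. The statistic function receives the permuted
#' label vector and must return a single number; a failing iteration is
#' resampled (and counted in the returned log).
#'
#' @param stat_fun Function of one argument (a label vector) returning a
#'   scalar statistic. The observed statistic is `stat_fun(labels)`.
#' @param labels Label vector to permute.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return An object of class `permutation_null` with elements `observed`,
#'   `null_values`, `b`, `p` and `n_failed`.
#' @export
label_shuffle_null <- function(stat_fun, labels, n_perm = 1000, seed = NULL) {
  with_seed(seed, {
    observed <- stat_fun(labels)
    null_values <- numeric(n_perm)
    n_failed <- 0L
    for (i in seq_len(n_perm)) {
      repeat {
        v <- tryCatch(stat_fun(sample(labels)), error = function(e) NULL)
        if (!is.null(v) && is.finite(v)) break
        n_failed <- n_failed + 1L
        if (n_failed > 10L * n_perm)
          stop("statistic failed on too many permuted label sets", call. = FALSE)
      }
      null_values[i] <- v
    }
    b <- sum(null_values >= observed)
    structure(list(observed = observed, null_values = null_values, b = b,
                   p = permutation_pvalue(b, n_perm), n_failed = n_failed),
              class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null: observed =", format(x$observed, digits = 4),
      " p =", format(x$p, digits = 4),
      sprintf("(b = %d, m = %d)\n", x$b, length(x$null_values)))
  invisible(x)
}

#' Maximum-statistic correction over a family of tests
#'
#' Controls the family-wise error rate by comparing each observed statistic
#' to the permutation distribution of the maximum statistic across all units
#' (sensors, searchlights, timepoints, ...).
#'
#' @param observed Numeric vector of observed statistics, one per unit.
#' @param null_stats Matrix of null statistics, iterations x units (or a
#'   vector when there is a single unit).
#' @return Numeric vector of corrected p-values, one per unit.
#' @export
maxstat_correct <- function(observed, null_stats) {
  if (is.vector(null_stats)) null_stats <- matrix(null_stats, ncol = 1L)
  if (ncol(null_stats) != length(observed))
    stop("'null_stats' columns must match length of 'observed'", call. = FALSE)
  m <- nrow(null_stats)
  maxima <- apply(null_stats, 1L, max)
  vapply(observed, function(o) permutation_pvalue(sum(maxima >= o), m),
         numeric(1))
}

#' FDR correction with temporal cluster filtering
#'
#' Applies Benjamini-Hochberg (or Benjamini-Yekutieli) FDR correction to a
#' timecourse of p-values, then removes runs of consecutive significant
#' timepoints shorter than `min_length`. The onset is the first sample of the
#' first surviving cluster.
#'
#' @param p Vector of per-timepoint p-values.
#' @param alpha FDR level (default 0.05).
#' @param min_length Minimum cluster length in samples (default 5).
#' @param method `"BH"` (default) or `"BY"`.
#' @return List with `sig_mask` (logical), `p_fdr`, `clusters` (data frame of
#'   start/end indices) and `onset_index` (`NA` when nothing survives).
#' @export
fdr_cluster <- function(p, alpha = 0.05, min_length = 5, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]", call. = FALSE)
  if (min_length < 1) stop("'min_length' must be >= 1", call. = FALSE)
  p_fdr <- p.adjust(p, method = method)
  raw_mask <- !is.na(p_fdr) & p_fdr < alpha
  r <- rle(raw_mask)
  keep <- r$values & r$lengths >= min_length
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig_mask <- raw_mask
  for (i in which(r$values & r$lengths < min_length))
    sig_mask[starts[i]:ends[i]] <- FALSE
  clusters <- data.frame(start = starts[keep], end = ends[keep])
  onset_index <- if (nrow(clusters)) clusters$start[1] else NA_integer_
  list(sig_mask = sig_mask, p_fdr = p_fdr, clusters = clusters,
       onset_index = onset_index)
}

#' Bias-corrected and accelerated bootstrap confidence interval of the mean
#'
#' BCa interval: the bias correction `z0` comes from the bootstrap CDF at the
#' observed mean and the acceleration from the jackknife skewness; both adjust
#' the percentile endpoints.
#'
#' @param x Numeric sample.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional RNG seed.
#' @param bias_correct,accelerate Set to `FALSE` to force `z0 = 0` /
#'   acceleration `= 0`; with both off the interval reduces to the plain
#'   percentile interval.
#' @return Numeric length-2 interval with attribute `"degenerate"` when all
#'   values are identical.
#' @export
bca_ci <- function(x, level = 0.95, n_boot = 1000, seed = NULL,
                   bias_correct = TRUE, accelerate = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(x)) == 1L)
    return(structure(c(x[1], x[1]), degenerate = TRUE))
  with_seed(seed, {
    obs <- mean(x)
    boots <- colMeans(matrix(x[sample.int(n, n * n_boot, replace = TRUE)], n))
    z0 <- if (bias_correct)
      qnorm((sum(boots < obs) + 0.5 * sum(boots == obs)) / n_boot)
    else 0
    if (!is.finite(z0)) z0 <- 0
    a <- 0
    if (accelerate) {
      jack <- (sum(x) - x) / (n - 1)
      d <- mean(jack) - jack
      denom <- 6 * sum(d^2)^1.5
      a <- if (denom > 0) sum(d^3) / denom else 0
    }
    zl <- qnorm((1 - level) / 2); zu <- -zl
    adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    unname(quantile(boots, c(adj(zl), adj(zu)), type = 6))
  })
}

#' Randomization tests on ERF window means
#'
#' Tests per-sensor condition differences of window-averaged evoked responses
#' across subjects with a paired t statistic (two conditions) or a
#' repeated-measures ANOVA F (two or more conditions). The null is built by
#' permuting condition assignment within each subject; corrected p-values use
#' the maximum-statistic distribution across sensors. The t statistic is
#' tested two-sided (via its absolute value).
#'
#' @param x Array subjects x sensors x conditions of window-averaged
#'   responses (dimnames on the condition axis are kept in the output).
#' @param contrast `"paired-t"` (exactly 2 conditions) or `"rm-anova"`.
#' @param n_perm Number of randomizations (default 5000).
#' @param seed Optional RNG seed.
#' @return Data frame with one row per sensor: `statistic`, `p_raw`,
#'   `p_corrected`.
#' @export
erf_window_tests <- function(x, contrast = c("paired-t", "rm-anova"),
                             n_perm = 5000, seed = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(length(dim(x)) == 3)
  ns <- dim(x)[1]; nsens <- dim(x)[2]; nc <- dim(x)[3]
  if (ns < 2) stop("need at least 2 subjects", call. = FALSE)
  if (contrast == "paired-t" && nc != 2)
    stop("paired-t requires exactly 2 conditions", call. = FALSE)
  finite0 <- function(v) { v[!is.finite(v)] <- 0; v }   # 0/0 when no effect
  stat_fun <- if (contrast == "paired-t") {
    function(arr) {
      d <- arr[, , 1] - arr[, , 2]
      if (is.null(dim(d))) d <- matrix(d, nrow = ns)
      finite0(abs(colMeans(d) / (apply(d, 2, sd) / sqrt(ns))))
    }
  } else {
    function(arr) {
      # one-way repeated-measures F per sensor
      vapply(seq_len(nsens), function(j) {
        y <- arr[, j, ]                      # subjects x conditions
        gm <- mean(y)
        ss_cond <- ns * sum((colMeans(y) - gm)^2)
        ss_subj <- nc * sum((rowMeans(y) - gm)^2)
        ss_tot <- sum((y - gm)^2)
        ss_err <- ss_tot - ss_cond - ss_subj
        (ss_cond / (nc - 1)) / (ss_err / ((nc - 1) * (ns - 1)))
      }, numeric(1)) |> finite0()
    }
  }
  with_seed(seed, {
    observed <- stat_fun(x)
    null_stats <- matrix(0, n_perm, nsens)
    for (i in seq_len(n_perm)) {
      xp <- x
      for (s in seq_len(ns)) xp[s, , ] <- x[s, , sample.int(nc)]
      null_stats[i, ] <- stat_fun(xp)
    }
    p_raw <- vapply(seq_len(nsens), function(j)
      permutation_pvalue(sum(null_stats[, j] >= observed[j]), n_perm), numeric(1))
    p_corrected <- maxstat_correct(observed, null_stats)
    data.frame(sensor = seq_len(nsens), statistic = observed,
               p_raw = p_raw, p_corrected = p_corrected)
  })
}

#' Proportion of subjects reaching significance per unit
#'
#' @param p Matrix of p-values, units x subjects.
#' @param alpha Significance level per subject (default 0.05).
#' @return Numeric vector in `[0, 1]`, one proportion per unit.
#' @export
group_proportion <- function(p, alpha = 0.05) {
  if (is.vector(p)) p <- matrix(p, nrow = 1L)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]", call. = FALSE)
  rowMeans(p < alpha)
}
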