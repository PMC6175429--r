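# Converting backward-model SVM weights into forward-model activation
# ("relevance") patterns, window/subject aggregation, and sign-flip
# permutation inference with max-statistic and Bonferroni control.

#' Transform classifier weights into an activation pattern
#'
#' Multiplies the weight vector by the feature covariance matrix,
#' `a = C w`: the backward-model weights become a forward-model activation
#' pattern that is interpretable as the signal pattern the classifier
#' exploits. With whitened features (`C = I`) the pattern equals the
#' weights. The pattern is defined up to positive scale; normalization is
#' applied at the map level.
#'
#' @param w Weight vector.
#' @param C Feature covariance (symmetric, PSD, matching `w`).
#' @return Numeric pattern vector.
#' @export
weights_to_pattern <- function(w, C) {
  if (length(w) != ncol(C) || nrow(C) != ncol(C))
    stop("dimension mismatch between weights and covariance", call. = FALSE)
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C), 1e-300))
    stop("covariance must be symmetric", call. = FALSE)
  as.vector(C %*% w)
}

default_relevance_windows <- function() {
  cbind(start = seq(0, 400, by = 100), end = seq(100, 500, by = 100))
}

#' Build a relevance map from source-space epochs
#'
#' For each timepoint the SVM is retrained on the full dataset (no
#' cross-validation, full-data standardization) to obtain the final model;
#' its weight vector is transformed into an activation pattern via the
#' feature covariance at that timepoint. Pattern magnitudes are averaged
#' within each time window, the mean over the baseline window is
#' subtracted per feature, and the map is normalized (max-abs = 1) per
#' subject.
#'
#' @param e Source-space `meg_epochs` (one channel per ROI), subaveraged.
#' @param pair Condition pair to decode.
#' @param windows Two-column matrix of window starts/ends in ms (default
#'   100 ms tiling of 0-500 ms, clipped to the epoch).
#' @param baseline Baseline window in seconds (default the pre-stimulus
#'   part of the epoch).
#' @param cost SVM box constraint.
#' @param signed Keep signed patterns instead of magnitudes (default
#'   `FALSE`: sign depends on the arbitrary class convention).
#' @param normalize `"subject"` (max-abs = 1, default) or `"none"`.
#' @return A `relevance_map`: `values` (ROIs x windows), `windows`,
#'   `baseline_value` per ROI, and metadata.
#' @export
build_relevance_map <- function(e, pair, windows = NULL,
                                baseline = NULL, cost = 1, signed = FALSE,
                                normalize = c("subject", "none")) {
  normalize <- match.arg(normalize)
  if (is.null(windows)) {
    windows <- default_relevance_windows()
    windows <- windows[windows[, 2] / 1000 <= max(e$times) + 1e-9, ,
                       drop = FALSE]
  }
  if (any(windows / 1000 < min(e$times) - 1e-9) ||
      any(windows / 1000 > max(e$times) + 1e-9))
    stop("relevance window outside the epoch", call. = FALSE)
  if (is.null(baseline)) baseline <- c(min(e$times), 0)
  ps <- pair_subset(e, pair)
  y <- as.character(ps$y)
  tp <- length(e$times)
  nroi <- dim(e$data)[2]
  patt <- matrix(0, nroi, tp)
  for (t in seq_len(tp)) {
    X <- e$data[ps$idx, , t, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = nroi)
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    fit <- fit_svm(Xs, y, cost = cost)
    a <- weights_to_pattern(svm_weight_vector(fit), cov(Xs))
    patt[, t] <- if (signed) a else abs(a)
  }
  nw <- nrow(windows)
  vals <- matrix(0, nroi, nw,
                 dimnames = list(e$channel_ids,
                                 sprintf("%d-%d ms", windows[, 1], windows[, 2])))
  for (w in seq_len(nw)) {
    idx <- window_indices(e$times, windows[w, ] / 1000)
    vals[, w] <- rowMeans(patt[, idx, drop = FALSE])
  }
  bidx <- window_indices(e$times, baseline)
  bval <- rowMeans(patt[, bidx, drop = FALSE])
  vals <- vals - bval
  if (normalize == "subject" && max(abs(vals)) > 0)
    vals <- vals / max(abs(vals))
  structure(list(values = vals, windows = windows, baseline = baseline,
                 baseline_value = bval, pair = sort(pair),
                 subject = e$subject, signed = signed,
                 normalize = normalize), class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("Relevance map [", x$subject, "]: ",
      nrow(x$values), " ROIs x ", ncol(x$values), " windows (",
      paste(x$pair, collapse = " vs "), ")\n", sep = "")
  pk <- arrayInd(which.max(x$values), dim(x$values))
  cat(sprintf("  peak %.3f at %s, %s\n", max(x$values),
              rownames(x$values)[pk[1]], colnames(x$values)[pk[2]]))
  invisible(x)
}

#' Sign-flip permutation test on group relevance maps
#'
#' Tests, per (ROI, window) cell, whether the group-mean baselined
#' relevance differs from zero. The null is built by randomly negating each
#' subject's whole map; per window, p-values are corrected across ROIs with
#' the maximum-statistic distribution, and the significance threshold is
#' Bonferroni-divided by the number of windows. The test is one-sided
#' (relevance above baseline).
#'
#' @param maps List of `relevance_map`s (or matrices), one per subject,
#'   with identical dimensions.
#' @param n_iter Number of sign-flip iterations (default 5000).
#' @param alpha Family-wise level before the Bonferroni division.
#' @param seed Optional RNG seed.
#' @return List with `observed` (group mean), `p` (max-statistic corrected,
#'   per cell), `sig` (logical, after Bonferroni over windows) and
#'   `alpha_cell` (the per-window threshold used).
#' @export
signflip_test <- function(maps, n_iter = 5000, alpha = 0.05, seed = NULL) {
  vals <- lapply(maps, function(m) if (inherits(m, "relevance_map")) m$values
                                   else as.matrix(m))
  ns <- length(vals)
  if (ns < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_iter < 100) warning("fewer than 100 sign-flip iterations")
  d <- dim(vals[[1]])
  arr <- array(unlist(vals), c(d[1], d[2], ns))
  observed <- apply(arr, c(1, 2), mean)
  nw <- d[2]
  p <- matrix(NA_real_, d[1], nw, dimnames = dimnames(vals[[1]]))
  with_seed(seed, {
    # null maxima per window across ROIs, shared flips across cells
    null_max <- matrix(0, n_iter, nw)
    for (i in seq_len(n_iter)) {
      fl <- sample(c(-1, 1), ns, replace = TRUE)
      m <- apply(sweep(arr, 3, fl, `*`), c(1, 2), mean)
      null_max[i, ] <- apply(m, 2, max)
    }
    for (w in seq_len(nw))
      p[, w] <- vapply(observed[, w], function(o)
        permutation_pvalue(sum(null_max[, w] >= o), n_iter), numeric(1))
  })
  alpha_cell <- alpha / nw
  list(observed = observed, p = p, sig = p < alpha_cell,
       alpha_cell = alpha_cell)
}

#' Export a relevance map to TSV
#'
#' One row per (subject, ROI, window) with value and significance flag.
#'
#' @param maps List of `relevance_map`s.
#' @param sig Optional significance matrix from [signflip_test()].
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_relevance_tsv <- function(maps, sig = NULL, path) {
  rows <- do.call(rbind, lapply(maps, function(m) {
    v <- m$values
    data.frame(subject = m$subject,
               roi = rep(rownames(v), ncol(v)),
               window = rep(colnames(v), each = nrow(v)),
               value = as.vector(v),
               sig = if (is.null(sig)) NA else as.vector(sig))
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rows)
}
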