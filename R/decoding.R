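# Time-resolved, sensor-set and searchlight decoding built on the linear SVM.

#' Seeded stratified fold assignment
#'
#' Assigns observations to `n_folds` folds so that per-fold class counts
#' differ from balance by at most one. Within each class the (optionally
#' seeded) random order is dealt round-robin; without a seed the assignment
#' is deterministic in trial order.
#'
#' @param y Label vector.
#' @param n_folds Number of folds (default 5).
#' @param seed Optional RNG seed.
#' @return Integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 5, seed = NULL) {
  if (n_folds < 2) stop("'n_folds' must be >= 2", call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds)
        stop("class '", cl, "' has fewer observations than folds", call. = FALSE)
      if (!is.null(seed)) idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

conf_to_metrics <- function(conf) {
  # conf: slices x 4 (tp, fn, fp, tn), positive class = +1
  n <- rowSums(conf)
  acc <- (conf[, 1] + conf[, 4]) / n
  f1 <- 2 * conf[, 1] / (2 * conf[, 1] + conf[, 2] + conf[, 3])
  list(accuracy = acc, f1 = f1)
}

std_code <- function(standardize) {
  match(match.arg(standardize, c("train", "pooled", "none")),
        c("none", "train", "pooled")) - 1L
}

#' Cross-validated linear-SVM decoding of a feature matrix
#'
#' Stratified k-fold cross-validation with per-fold standardization:
#' z-scoring parameters are estimated on the training split only and applied
#' to the held-out split (`standardize = "train"`, the default).
#' `"pooled"` deliberately estimates them on the full data — a leaky variant
#' retained only for the leakage-detection control — and `"none"` disables
#' scaling. Accuracy is pooled over folds (proportion of correctly classified
#' cases); F1 is computed on the pooled confusion matrix with the
#' alphabetically first class as the positive class.
#'
#' @param x Observations x features matrix.
#' @param y Binary labels.
#' @param n_folds Number of stratified folds (default 5).
#' @param cost SVM box constraint (default 1).
#' @param standardize `"train"`, `"pooled"` or `"none"`.
#' @param seed Optional seed for the fold assignment.
#' @param folds Optional explicit fold ids (overrides `n_folds`/`seed`).
#' @return List with `accuracy`, `f1` and the `folds` used.
#' @export
crossval_decode <- function(x, y, n_folds = 5, cost = 1,
                            standardize = "train", seed = NULL, folds = NULL) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("'y' must be binary", call. = FALSE)
  ys <- ifelse(as.character(y) == lev[1], 1, -1)
  if (is.null(folds)) folds <- stratified_folds(y, n_folds, seed)
  cube <- array(x, c(nrow(x), ncol(x), 1L))
  conf <- .cpp_cv_cube(cube, ys, as.integer(folds), cost, std_code(standardize),
                       1e-6, 100000L)
  m <- conf_to_metrics(conf)
  list(accuracy = m$accuracy[1], f1 = m$f1[1], folds = folds, levels = lev)
}

resolve_channels <- function(e, channels) {
  ids <- e$channel_ids
  if (is.null(channels)) return(seq_along(ids))
  if (is.numeric(channels)) return(as.integer(channels))
  if (length(channels) == 1L && !is.null(e$array) &&
      channels %in% levels(e$array$groups))
    return(which(e$array$groups == channels))
  idx <- match(channels, ids)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

pair_subset <- function(e, pair) {
  stopifnot(length(pair) == 2)
  keep <- which(as.character(e$labels) %in% pair)
  if (!length(keep)) stop("no trials for pair ", paste(pair, collapse = "/"),
                          call. = FALSE)
  list(idx = keep, y = factor(as.character(e$labels)[keep], levels = sort(pair)))
}

#' Time-resolved decoding of an epoch set
#'
#' At each sampled timepoint the feature vector is the instantaneous value of
#' the selected channels; a stratified cross-validated linear SVM is trained
#' and tested independently per timepoint. Inference fields (p-values,
#' significance mask, onset) are filled by [decode_inference()].
#'
#' @param e A `meg_epochs` object (typically after [subaverage()]).
#' @param pair Character vector of two condition labels.
#' @param channels Channel subset: indices, channel ids, an anatomical group
#'   name (`"occipital"`, `"temporal"`, `"parietal"`, `"frontocentral"`) or
#'   `NULL` for all channels.
#' @param n_folds,cost,standardize,seed Passed to the cross-validation core.
#' @return A `decoding_result` with per-timepoint `accuracy` and `f1`.
#' @export
timeresolved_decode <- function(e, pair, channels = NULL, n_folds = 5,
                                cost = 1, standardize = "train", seed = NULL) {
  chidx <- resolve_channels(e, channels)
  if (!length(chidx)) stop("empty channel subset", call. = FALSE)
  ps <- pair_subset(e, pair)
  cube <- e$data[ps$idx, chidx, , drop = FALSE]
  y <- ps$y
  ys <- ifelse(as.character(y) == levels(y)[1], 1, -1)
  folds <- stratified_folds(y, n_folds, seed)
  conf <- .cpp_cv_cube(cube, ys, as.integer(folds), cost, std_code(standardize),
                       1e-6, 100000L)
  m <- conf_to_metrics(conf)
  structure(list(
    times = e$times, accuracy = m$accuracy, f1 = m$f1,
    pair = sort(pair), channels = e$channel_ids[chidx], n_obs = length(y),
    folds = folds, cost = cost, standardize = standardize, sfreq = e$sfreq,
    p_raw = NULL, p_fdr = NULL, sig_mask = NULL, onset_ms = NA_real_,
    data_cube = cube, y = y), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Time-resolved decoding:", paste(x$pair, collapse = " vs "), "\n")
  cat(sprintf("  %d observations, %d channels, %d timepoints\n",
              x$n_obs, length(x$channels), length(x$times)))
  cat(sprintf("  peak accuracy %.3f at %.0f ms\n",
              max(x$accuracy), 1000 * x$times[which.max(x$accuracy)]))
  if (!is.null(x$sig_mask)) {
    if (is.finite(x$onset_ms))
      cat(sprintf("  onset of significant decoding: %.1f ms\n", x$onset_ms))
    else cat("  no significant cluster\n")
  }
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  graphics::plot(x$times * 1000, x$accuracy, type = "l",
                 xlab = "time (ms)", ylab = "accuracy",
                 main = paste(x$pair, collapse = " vs "), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  graphics::abline(v = 0, lty = 3)
  if (!is.null(x$sig_mask) && any(x$sig_mask))
    graphics::points(x$times[x$sig_mask] * 1000,
                     rep(min(x$accuracy), sum(x$sig_mask)),
                     pch = 15, col = "firebrick", cex = 0.5)
  invisible(x)
}

#' Permutation inference for a decoding timecourse
#'
#' Builds a label-shuffle null for the cross-validated accuracy timecourse:
#' labels are permuted across all observations (training and test sets) and
#' stratified folds reassigned per permutation. Per-timepoint p-values are
#' FDR-adjusted and cluster-filtered ([fdr_cluster()]); the peak accuracy is
#' additionally tested against the maximum-over-time null distribution
#' (`p_peak_corrected`) and, mirroring the fixed-timepoint convention, against
#' the null at the observed peak sample only (`p_peak_observed`, reported for
#' comparison — it ignores the selection of the peak).
#'
#' @param result A `decoding_result` from [timeresolved_decode()].
#' @param n_perm Number of label permutations (default 1000).
#' @param alpha FDR level.
#' @param min_length Minimum cluster length in samples (default 5).
#' @param seed Optional RNG seed.
#' @param return_null Keep the permutation accuracy matrix in the output.
#' @return The `decoding_result` with `p_raw`, `p_fdr`, `sig_mask`,
#'   `clusters`, `onset_ms`, `p_peak_corrected` and `p_peak_observed` filled.
#' @export
decode_inference <- function(result, n_perm = 1000, alpha = 0.05,
                             min_length = 5, seed = NULL, return_null = FALSE) {
  stopifnot(inherits(result, "decoding_result"))
  cube <- result$data_cube
  if (is.null(cube)) stop("result does not carry its feature data", call. = FALSE)
  y <- result$y
  n <- length(y)
  ymat <- matrix(0, n, n_perm)
  foldmat <- matrix(0L, n, n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      yp <- sample(as.character(y))
      ymat[, i] <- ifelse(yp == levels(y)[1], 1, -1)
      foldmat[, i] <- stratified_folds(yp, max(result$folds),
                                       seed = sample.int(2^30, 1))
    }
  })
  null_acc <- .cpp_null_cube(cube, ymat, foldmat, result$cost,
                             std_code(result$standardize), 1e-6, 100000L)
  acc <- result$accuracy
  result$p_raw <- vapply(seq_along(acc), function(t)
    permutation_pvalue(sum(null_acc[, t] >= acc[t]), n_perm), numeric(1))
  fc <- fdr_cluster(result$p_raw, alpha = alpha, min_length = min_length)
  result$p_fdr <- fc$p_fdr
  result$sig_mask <- fc$sig_mask
  result$clusters <- fc$clusters
  result$onset_ms <- if (is.na(fc$onset_index)) NA_real_
                     else 1000 * result$times[fc$onset_index]
  pk <- which.max(acc)
  null_max <- apply(null_acc, 1L, max)
  result$p_peak_corrected <- permutation_pvalue(sum(null_max >= acc[pk]), n_perm)
  result$p_peak_observed <- permutation_pvalue(sum(null_acc[, pk] >= acc[pk]),
                                               n_perm)
  if (return_null) result$null_acc <- null_acc
  result
}

#' Searchlight decoding over sensor neighborhoods
#'
#' For every channel (centroid), the features are the values of the centroid
#' plus its directly connected neighbors over a short sliding window
#' (default 10 samples, ~16 ms at 600 Hz); consecutive non-overlapping
#' windows tile the epoch. Each searchlight/window is decoded with stratified
#' cross-validation; the per-subject p-value is computed by label permutation
#' at the subject's peak post-stimulus window (or at a caller-fixed window,
#' for the group-peak convention).
#'
#' @param e A `meg_epochs` object (typically after [subaverage()]).
#' @param pair Condition pair to decode.
#' @param window_samples Samples per window (default 10).
#' @param n_folds,cost,standardize Passed to the cross-validation core.
#' @param n_perm Label permutations for the per-centroid p-value.
#' @param seed Optional RNG seed.
#' @param at_window Optional fixed window index at which to evaluate the
#'   permutation test; default `NULL` uses each centroid's own peak
#'   post-stimulus window.
#' @return A `searchlight_result`: `accuracy` (centroids x windows),
#'   `windows` (start/end seconds), `p`, `peak_window` and searchlight
#'   `sizes` (number of sensors, flagged when 1).
#' @export
searchlight_decode <- function(e, pair, window_samples = 10, n_folds = 5,
                               cost = 1, standardize = "train", n_perm = 199,
                               seed = NULL, at_window = NULL) {
  if (is.null(e$array) || is.null(e$array$neighbors))
    stop("epochs carry no sensor array / neighbor graph", call. = FALSE)
  ps <- pair_subset(e, pair)
  y <- ps$y
  ys <- ifelse(as.character(y) == levels(y)[1], 1, -1)
  ntp <- length(e$times)
  nwin <- ntp %/% window_samples
  if (nwin < 1) stop("epoch shorter than one window", call. = FALSE)
  win_idx <- lapply(seq_len(nwin), function(w)
    ((w - 1) * window_samples + 1):(w * window_samples))
  windows <- data.frame(
    start = vapply(win_idx, function(i) e$times[i[1]], numeric(1)),
    end = vapply(win_idx, function(i) e$times[i[length(i)]], numeric(1)))
  nch <- length(e$channel_ids)
  folds <- stratified_folds(y, n_folds, derive_seed(seed, 1L))
  acc <- matrix(NA_real_, nch, nwin,
                dimnames = list(e$channel_ids, NULL))
  sizes <- integer(nch)
  post <- which(windows$start >= 0)
  if (!length(post)) post <- seq_len(nwin)
  p <- numeric(nch); peak_window <- integer(nch)
  n <- length(y)
  ymat <- matrix(0, n, n_perm); foldmat <- matrix(0L, n, n_perm)
  with_seed(derive_seed(seed, 2L) %||% NULL, {
    for (i in seq_len(n_perm)) {
      yp <- sample(as.character(y))
      ymat[, i] <- ifelse(yp == levels(y)[1], 1, -1)
      foldmat[, i] <- stratified_folds(yp, n_folds, sample.int(2^30, 1))
    }
  })
  for (ch in seq_len(nch)) {
    nb <- sort(unique(c(ch, e$array$neighbors[[ch]])))
    sizes[ch] <- length(nb)
    feats <- e$data[ps$idx, nb, , drop = FALSE]
    cube <- array(NA_real_, c(n, length(nb) * window_samples, nwin))
    for (w in seq_len(nwin))
      cube[, , w] <- matrix(feats[, , win_idx[[w]], drop = FALSE], nrow = n)
    conf <- .cpp_cv_cube(cube, ys, as.integer(folds), cost,
                         std_code(standardize), 1e-6, 100000L)
    acc[ch, ] <- conf_to_metrics(conf)$accuracy
    pw <- if (is.null(at_window)) post[which.max(acc[ch, post])] else at_window
    peak_window[ch] <- pw
    null_acc <- .cpp_null_cube(cube[, , pw, drop = FALSE], ymat, foldmat, cost,
                               std_code(standardize), 1e-6, 100000L)
    p[ch] <- permutation_pvalue(sum(null_acc[, 1] >= acc[ch, pw]), n_perm)
  }
  if (any(sizes == 1L))
    warning("searchlight(s) of size 1 (centroid without neighbors): ",
            paste(e$channel_ids[sizes == 1L], collapse = ", "))
  structure(list(accuracy = acc, windows = windows, p = setNames(p, e$channel_ids),
                 peak_window = peak_window, sizes = setNames(sizes, e$channel_ids),
                 pair = sort(pair), n_perm = n_perm),
            class = "searchlight_result")
}

#' @export
print.searchlight_result <- function(x, ...) {
  cat("Searchlight decoding:", paste(x$pair, collapse = " vs "), "\n")
  cat(sprintf("  %d centroids x %d windows; searchlight sizes %d-%d (mean %.2f)\n",
              nrow(x$accuracy), ncol(x$accuracy), min(x$sizes), max(x$sizes),
              mean(x$sizes)))
  cat(sprintf("  %d centroid(s) with p < .05\n", sum(x$p < 0.05)))
  invisible(x)
}

#' Collapse emotion labels into a single face category
#'
#' Relabels every non-scrambled trial as `"face"`, producing the orthogonal
#' face-vs-scrambled contrast used for feature selection: the collapsed
#' labels are invariant under any permutation of the emotion labels, which
#' is what makes the selection unbiased for emotion decoding.
#'
#' @param e A `meg_epochs` object.
#' @param scrambled Label of the scrambled condition.
#' @param face_label Replacement label for all other conditions.
#' @return `meg_epochs` with two-level labels.
#' @export
relabel_faces <- function(e, scrambled = "scrambled", face_label = "face") {
  lab <- as.character(e$labels)
  lab[lab != scrambled] <- face_label
  e$labels <- factor(lab, levels = c(face_label, scrambled))
  e
}

#' Group map of searchlight significance
#'
#' Combines per-subject searchlight p-values into the proportion of subjects
#' reaching significance at each centroid.
#'
#' @param results List of `searchlight_result`, one per subject.
#' @param alpha Per-subject significance level (default 0.05).
#' @return Named numeric vector of proportions per centroid.
#' @export
searchlight_group <- function(results, alpha = 0.05) {
  pmat <- do.call(cbind, lapply(results, `[[`, "p"))
  setNames(group_proportion(pmat, alpha), rownames(pmat))
}

#' Orthogonal-contrast feature selection
#'
#' Selects the channels whose group proportion of significant subjects
#' reaches `required_fraction`. By design this must be computed on a contrast
#' orthogonal to the one subsequently decoded (face vs scrambled, never the
#' emotion contrast), so the selection cannot bias the emotion decoding.
#'
#' @param group_prop Named proportion vector from [searchlight_group()].
#' @param required_fraction Minimum proportion (default 1.0, i.e. all
#'   subjects significant).
#' @return Character vector of selected channel ids (possibly empty).
#' @export
select_features <- function(group_prop, required_fraction = 1.0) {
  sel <- names(group_prop)[group_prop >= required_fraction - 1e-12]
  if (!length(sel)) {
    message("feature selection returned an empty channel set")
    sel <- character(0)
  }
  sel
}

#' Group-level inference on decoding timecourses
#'
#' Averages per-subject accuracy timecourses and tests the group mean against
#' the average of the per-subject label-shuffle nulls (the null is computed
#' in the same way as the observed statistic), followed by FDR adjustment and
#' temporal cluster filtering. Optionally adds per-timepoint BCa intervals of
#' the across-subject mean accuracy.
#'
#' @param results List of `decoding_result`s processed by
#'   [decode_inference()] with `return_null = TRUE`.
#' @param alpha FDR level.
#' @param min_length Minimum cluster length (samples).
#' @param ci Logical: compute per-timepoint BCa intervals (needs >= 3
#'   subjects).
#' @param seed Optional RNG seed for the bootstrap.
#' @return List with `times`, `accuracy` (group mean), `p_raw`, `p_fdr`,
#'   `sig_mask`, `clusters`, `onset_ms` and optional `ci95` (2 x timepoints).
#' @export
group_decode_inference <- function(results, alpha = 0.05, min_length = 5,
                                   ci = FALSE, seed = NULL) {
  accs <- do.call(rbind, lapply(results, `[[`, "accuracy"))
  nulls <- lapply(results, `[[`, "null_acc")
  if (any(vapply(nulls, is.null, logical(1))))
    stop("run decode_inference(..., return_null = TRUE) per subject first",
         call. = FALSE)
  gnull <- Reduce(`+`, nulls) / length(nulls)   # perms x timepoints
  gacc <- colMeans(accs)
  n_perm <- nrow(gnull)
  p_raw <- vapply(seq_along(gacc), function(t)
    permutation_pvalue(sum(gnull[, t] >= gacc[t]), n_perm), numeric(1))
  fc <- fdr_cluster(p_raw, alpha = alpha, min_length = min_length)
  times <- results[[1]]$times
  out <- list(times = times, accuracy = gacc, subject_accuracy = accs,
              p_raw = p_raw, p_fdr = fc$p_fdr, sig_mask = fc$sig_mask,
              clusters = fc$clusters,
              onset_ms = if (is.na(fc$onset_index)) NA_real_
                         else 1000 * times[fc$onset_index])
  if (ci && nrow(accs) >= 3) {
    out$ci95 <- vapply(seq_along(gacc), function(t)
      tryCatch(bca_ci(accs[, t], seed = derive_seed(seed, t)),
               error = function(e) c(NA_real_, NA_real_)), numeric(2))
  }
  out
}
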