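# Filtering, baseline correction, motion-based rejection, pseudo-trial
# averaging, evoked responses, global field power and component windows.

#' Filter specification
#'
#' @param kind `"bandpass"` (IIR Butterworth, applied forward-backward) or
#'   `"comb"` (cascaded IIR notches at a base frequency and its harmonics).
#' @param band For `"bandpass"`, `c(low, high)` in Hz; for `"comb"`, the
#'   base (mains) frequency in Hz.
#' @param order Butterworth order (default 4).
#' @param q Notch quality factor for the comb (default 35).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("bandpass", "comb"), band, order = 4, q = 35) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
      stop("bandpass needs 0 < low < high", call. = FALSE)
  } else if (length(band) != 1 || band <= 0) {
    stop("comb needs a positive base frequency", call. = FALSE)
  }
  structure(list(kind = kind, band = band, order = order, q = q),
            class = "filter_spec")
}

# RBJ biquad notch coefficients
notch_coef <- function(f0, sfreq, q) {
  w0 <- 2 * pi * f0 / sfreq
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

filter_coefs <- function(spec, sfreq) {
  nyq <- sfreq / 2
  if (spec$kind == "bandpass") {
    if (spec$band[2] >= nyq)
      stop("band edge ", spec$band[2], " Hz not below Nyquist (", nyq, " Hz)",
           call. = FALSE)
    # cascade of high- and low-pass halves: better conditioned than the
    # direct band-pass polynomial when the band spans several decades
    hp <- signal::butter(spec$order, spec$band[1] / nyq, type = "high")
    lp <- signal::butter(spec$order, spec$band[2] / nyq, type = "low")
    for (bf in list(hp, lp))
      if (any(Mod(polyroot(rev(bf$a))) > 1 - 1e-10))
        stop("unstable Butterworth design at order ", spec$order,
             "; reduce the order or widen the band", call. = FALSE)
    list(list(b = hp$b, a = hp$a), list(b = lp$b, a = lp$a))
  } else {
    freqs <- seq(spec$band, nyq - 1e-9, by = spec$band)
    if (!length(freqs))
      stop("comb base frequency above Nyquist", call. = FALSE)
    lapply(freqs, notch_coef, sfreq = sfreq, q = spec$q)
  }
}

#' Apply a zero-phase filter to every trial and channel
#'
#' Filters are applied forward and backward (zero phase), so evoked
#' latencies are not shifted; the filter chain is recorded in the epoch
#' metadata.
#'
#' @param e A `meg_epochs` object.
#' @param spec A [filter_spec()].
#' @return Filtered `meg_epochs`.
#' @export
apply_filter <- function(e, spec) {
  coefs <- filter_coefs(spec, e$sfreq)
  d <- dim(e$data)
  x <- matrix(aperm(e$data, c(3, 1, 2)), nrow = d[3])  # tp x (trials*ch)
  for (co in coefs)
    x <- apply(x, 2, function(v) signal::filtfilt(co$b, co$a, v))
  e$data <- aperm(array(x, c(d[3], d[1], d[2])), c(2, 3, 1))
  e$meta$filters <- c(e$meta$filters,
                      if (spec$kind == "bandpass")
                        sprintf("butterworth(%g-%g Hz, order %d, zero-phase)",
                                spec$band[1], spec$band[2], spec$order)
                      else sprintf("comb(%g Hz, Q=%g, zero-phase)",
                                   spec$band, spec$q))
  e
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default the 500 ms before stimulus onset).
#'
#' @param e A `meg_epochs` object.
#' @param window Baseline window in seconds (default `c(-0.5, 0)`).
#' @return Baseline-corrected `meg_epochs`.
#' @export
baseline_correct <- function(e, window = c(-0.5, 0)) {
  idx <- window_indices(e$times, window)
  bl <- apply(e$data[, , idx, drop = FALSE], c(1, 2), mean)
  e$data <- e$data - as.vector(bl)   # recycles over the time dimension
  e$meta$baseline <- window
  e
}

#' Reject trials by coil motion
#'
#' Removes trials whose maximum displacement of any fiducial coil (distance
#' from the coil position at trial start, maximized over samples) exceeds
#' the threshold. Rejection is label-blind.
#'
#' @param e A `meg_epochs` object with coil traces.
#' @param threshold Displacement threshold in mm (default 5).
#' @return List with `epochs` (trials removed), `report` (per-condition
#'   kept/removed counts), `removed` (trial indices) and `max_displacement`
#'   per trial. Without coil traces the data pass through with a warning and
#'   `report = NULL`.
#' @export
reject_trials <- function(e, threshold = 5) {
  if (is.null(e$coil_traces)) {
    warning("no coil traces present; trials pass through unchecked")
    e$meta$motion_checked <- FALSE
    return(list(epochs = e, report = NULL, removed = integer(0),
                max_displacement = NULL))
  }
  md <- apply(e$coil_traces, 1, max)     # max over coils and samples
  removed <- which(md > threshold)
  keep <- setdiff(seq_along(md), removed)
  report <- data.frame(condition = levels(e$labels),
                       removed = as.integer(table(e$labels[removed])),
                       kept = as.integer(table(e$labels[keep])))
  e$data <- e$data[keep, , , drop = FALSE]
  e$labels <- droplevels(e$labels[keep])
  e$coil_traces <- e$coil_traces[keep, , , drop = FALSE]
  if (!is.null(e$eog)) e$eog <- e$eog[keep, , , drop = FALSE]
  e$meta$motion_checked <- TRUE
  e$meta$motion_threshold <- threshold
  list(epochs = e, report = report, removed = removed, max_displacement = md)
}

#' Average trials into pseudo-trials
#'
#' Within each condition, trials are randomly partitioned (seeded) into
#' groups of `group_size` and each group averaged into one pseudo-trial;
#' remainder trials are discarded so pseudo-trial SNR stays homogeneous.
#'
#' @param e A `meg_epochs` object.
#' @param group_size Trials per pseudo-trial (default 5).
#' @param seed Optional RNG seed for the partition.
#' @return `meg_epochs` of pseudo-trials (coil traces dropped; EOG averaged
#'   the same way as the MEG data).
#' @export
subaverage <- function(e, group_size = 5, seed = NULL) {
  if (group_size < 1) stop("'group_size' must be >= 1", call. = FALSE)
  conds <- levels(e$labels)
  sel <- list(); lab <- character(0)
  with_seed(seed, {
    for (cl in conds) {
      idx <- which(e$labels == cl)
      ng <- length(idx) %/% group_size
      if (ng == 0) {
        warning("condition '", cl, "' has fewer than ", group_size,
                " trials; no pseudo-trials produced")
        next
      }
      idx <- idx[sample.int(length(idx))]
      for (g in seq_len(ng)) {
        sel[[length(sel) + 1L]] <- idx[((g - 1) * group_size + 1):(g * group_size)]
        lab <- c(lab, cl)
      }
    }
  })
  np <- length(sel)
  d <- dim(e$data)
  data <- array(0, c(np, d[2], d[3]))
  eog <- if (!is.null(e$eog)) array(0, c(np, dim(e$eog)[2], dim(e$eog)[3]))
  for (i in seq_len(np)) {
    data[i, , ] <- apply(e$data[sel[[i]], , , drop = FALSE], c(2, 3), mean)
    if (!is.null(eog))
      eog[i, , ] <- apply(e$eog[sel[[i]], , , drop = FALSE], c(2, 3), mean)
  }
  e$data <- data
  e$labels <- factor(lab, levels = conds)
  e$eog <- eog
  e$coil_traces <- NULL
  e$meta$subaveraged <- group_size
  e
}

#' Per-condition evoked responses
#'
#' @param e A `meg_epochs` object.
#' @param conditions Conditions to include (default all).
#' @return A `meg_evoked`: list of channels x timepoints matrices (one per
#'   condition), trial counts, and the time axis of the source epochs.
#' @export
compute_evoked <- function(e, conditions = levels(e$labels)) {
  unknown <- setdiff(conditions, levels(e$labels))
  if (length(unknown)) stop("unknown condition(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  data <- lapply(conditions, function(cl) {
    idx <- which(e$labels == cl)
    if (!length(idx)) stop("no trials for condition '", cl, "'", call. = FALSE)
    apply(e$data[idx, , , drop = FALSE], c(2, 3), mean)
  })
  structure(list(data = setNames(data, conditions),
                 n_trials = setNames(vapply(conditions, function(cl)
                   sum(e$labels == cl), numeric(1)), conditions),
                 times = e$times, channel_ids = e$channel_ids,
                 sfreq = e$sfreq), class = "meg_evoked")
}

#' Global field power of an evoked response
#'
#' The GFP at each timepoint is the across-channel standard deviation of the
#' grand-average (trial-count weighted over the requested conditions) evoked
#' response; an RMS variant is available.
#'
#' @param v A `meg_evoked`.
#' @param conditions Conditions entering the grand average (default all).
#' @param type `"sd"` (default) or `"rms"`.
#' @return Numeric GFP timecourse.
#' @export
global_field_power <- function(v, conditions = names(v$data),
                               type = c("sd", "rms")) {
  type <- match.arg(type)
  w <- v$n_trials[conditions] / sum(v$n_trials[conditions])
  ga <- Reduce(`+`, Map(`*`, v$data[conditions], w))
  if (type == "sd") apply(ga, 2, sd) else sqrt(colMeans(ga^2))
}

#' Identify component windows from local GFP minima
#'
#' Window boundaries are placed at the deepest interior local minima of the
#' (lightly smoothed) GFP inside the search range, plus the range endpoints:
#' `n_windows` windows require `n_windows - 1` minima.
#'
#' @param gfp GFP timecourse.
#' @param times Time axis in seconds matching `gfp`.
#' @param search_range Search range in ms (default `c(50, 350)`).
#' @param n_windows Number of windows (default 3).
#' @param smooth_ms Moving-average width in ms before minima detection.
#' @param labels Window labels (defaults to `M100`/`M170`/`M220` for 3).
#' @return Data frame `label`, `t_start`, `t_end` (ms), ordered and
#'   non-overlapping.
#' @export
find_component_windows <- function(gfp, times, search_range = c(50, 350),
                                   n_windows = 3, smooth_ms = 10,
                                   labels = NULL) {
  tms <- times * 1000
  idx <- which(tms >= search_range[1] & tms <= search_range[2])
  if (length(idx) < 5) stop("search range too narrow", call. = FALSE)
  k <- max(1L, round(smooth_ms / 1000 * 1 / mean(diff(times))))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.vector(stats::filter(gfp, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- gfp[is.na(sm)]
  g <- sm[idx]
  interior <- which(diff(sign(diff(g))) > 0) + 1L  # strictly lower than both
  if (length(interior) < n_windows - 1)
    stop("found only ", length(interior), " interior GFP minima at ",
         paste(round(tms[idx][interior]), collapse = ", "),
         " ms; need ", n_windows - 1, call. = FALSE)
  picked <- interior[order(g[interior])][seq_len(n_windows - 1)]
  bounds <- sort(c(search_range[1], tms[idx][picked], search_range[2]))
  if (is.null(labels))
    labels <- if (n_windows == 3) c("M100", "M170", "M220")
              else sprintf("W%d", seq_len(n_windows))
  data.frame(label = labels, t_start = bounds[-length(bounds)],
             t_end = bounds[-1])
}

#' Canonical component windows
#'
#' The default M100/M170/M220 windows (60-127, 127-173, 173-317 ms) used
#' when data-driven detection is disabled.
#' @return Data frame `label`, `t_start`, `t_end` in ms.
#' @export
default_component_windows <- function() {
  data.frame(label = c("M100", "M170", "M220"),
             t_start = c(60, 127, 173), t_end = c(127, 173, 317))
}

#' Window-averaged evoked responses
#'
#' Averages each condition's evoked response within each component window.
#'
#' @param v A `meg_evoked`.
#' @param windows Data frame as returned by [find_component_windows()].
#' @return Array conditions x channels x windows.
#' @export
evoked_window_means <- function(v, windows = default_component_windows()) {
  nch <- length(v$channel_ids)
  out <- array(NA_real_, c(length(v$data), nch, nrow(windows)),
               dimnames = list(names(v$data), v$channel_ids, windows$label))
  for (w in seq_len(nrow(windows))) {
    idx <- window_indices(v$times, c(windows$t_start[w], windows$t_end[w]) / 1000)
    for (cl in seq_along(v$data))
      out[cl, , w] <- rowMeans(v$data[[cl]][, idx, drop = FALSE])
  }
  out
}
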