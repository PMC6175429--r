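# Synthetic multi-subject MEG generator with known ground truth: evoked
# components, condition effects injected as additive low-rank spatiotemporal
# patterns, 1/f-plus-white sensor noise, EOG transients and fiducial-coil
# motion traces.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic MEG generator. Defaults emulate
#' the acquisition and design of a typical emotional-face MEG study: 14
#' subjects, four conditions (angry, happy, neutral, scrambled) with 180
#' trials each, 600 Hz sampling over -0.5..1 s epochs, three evoked
#' components (M100/M170/M220-like), a strong face-vs-scrambled multivariate
#' effect from 80 ms and smaller pairwise emotion effects with onsets of
#' 90-113 ms, spatially correlated 1/f noise plus white sensor noise,
#' condition-independent EOG blinks, and coil displacement kept below the
#' 5 mm rejection threshold.
#'
#' @param n_subjects,n_trials_per_condition Counts.
#' @param conditions Condition labels.
#' @param sfreq Sampling rate in Hz.
#' @param epoch_window Epoch limits in seconds relative to stimulus onset;
#'   the onset (t = 0) always falls on a sample.
#' @param evoked_components List of components, each
#'   `list(latency, width, amplitude, seed)` (ms, ms, a.u., topography seed).
#'   Component topographies are shared across conditions and subjects, so
#'   condition means differ only through `effect_spec`.
#' @param effect_spec List of injected condition effects, each
#'   `list(pair, onset, duration, amplitude, seed, channels = NULL)` (ms,
#'   ms, a.u.): half the pattern is added to trials of `pair[1]` and half
#'   subtracted from trials of `pair[2]`; the token `"faces"` expands to all
#'   non-scrambled conditions. `channels` restricts the effect topography to
#'   a channel subset (localized effects for searchlight ground truth).
#' @param noise `list(white_sd, pink_sd, exponent, spatial_scale)`: white
#'   sensor noise (uncorrelated), 1/f "brain" noise with the given spectral
#'   exponent, spatially mixed with Gaussian kernel scale in meters.
#' @param eog `list(blink_rate, amplitude, correlate_pair,
#'   correlate_strength)`: blink rate in Hz; set `correlate_pair` to a
#'   condition pair to make blinks label-dependent (positive control for the
#'   EOG-decoding check).
#' @param motion `list(step_sd, max_displacement, n_coils, decimation)`:
#'   bounded-random-walk coil displacement in mm; default bound 3 mm, below
#'   the 5 mm rejection threshold.
#' @param ramp_ms Rise time of the smoothed boxcar carrying each effect.
#' @param seed Master RNG seed; fully determines the output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_subjects = 14, n_trials_per_condition = 180,
    conditions = c("angry", "happy", "neutral", "scrambled"),
    sfreq = 600, epoch_window = c(-0.5, 1.0),
    evoked_components = list(
      list(latency = 100, width = 35, amplitude = 1.0, seed = 101),
      list(latency = 160, width = 40, amplitude = 1.2, seed = 102),
      list(latency = 240, width = 60, amplitude = 0.8, seed = 103)),
    effect_spec = list(
      list(pair = c("faces", "scrambled"), onset = 80, duration = 600,
           amplitude = 1.0, seed = 201),
      list(pair = c("angry", "neutral"), onset = 90, duration = 400,
           amplitude = 0.4, seed = 202),
      list(pair = c("angry", "happy"), onset = 90, duration = 400,
           amplitude = 0.35, seed = 203),
      list(pair = c("happy", "neutral"), onset = 113, duration = 400,
           amplitude = 0.3, seed = 204)),
    noise = list(white_sd = 0.3, pink_sd = 1.0, exponent = 1.0,
                 spatial_scale = 0.04),
    eog = list(blink_rate = 0.15, amplitude = 20, correlate_pair = NULL,
               correlate_strength = 0),
    motion = list(step_sd = 0.05, max_displacement = 3, n_coils = 3,
                  decimation = 10),
    ramp_ms = 20, seed = 1) {
  cfg <- list(n_subjects = n_subjects,
              n_trials_per_condition = n_trials_per_condition,
              conditions = conditions, sfreq = sfreq,
              epoch_window = epoch_window,
              evoked_components = evoked_components,
              effect_spec = effect_spec, noise = noise, eog = eog,
              motion = motion, ramp_ms = ramp_ms, seed = seed)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_trials_per_condition >= 1,
            length(cfg$conditions) >= 1, cfg$sfreq > 0,
            cfg$epoch_window[1] < cfg$epoch_window[2])
  for (ef in cfg$effect_spec) {
    if (ef$amplitude < 0) stop("effect amplitude must be >= 0", call. = FALSE)
    if (ef$onset < cfg$epoch_window[1] * 1000 ||
        ef$onset > cfg$epoch_window[2] * 1000)
      stop("effect onset ", ef$onset, " ms outside the epoch window",
           call. = FALSE)
  }
  for (ev in cfg$evoked_components)
    if (ev$amplitude < 0) stop("evoked amplitude must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Epoched MEG container
#'
#' Assembles and validates the package's epoch container: a trials x
#' channels x timepoints array with its time axis, per-trial condition
#' labels, sensor array, coil displacement traces and EOG channels.
#'
#' @param data Numeric array trials x channels x timepoints.
#' @param times Time axis in seconds; must be regular with step `1/sfreq`
#'   and include t = 0 as a sample (when 0 lies inside the window).
#' @param labels Condition label per trial.
#' @param sfreq Sampling rate (Hz).
#' @param array Optional `sensor_array`.
#' @param subject Subject identifier.
#' @param coil_traces Optional array trials x coils x samples of coil
#'   displacement (mm, relative to trial start).
#' @param eog Optional array trials x 2 x timepoints.
#' @param units Unit string recorded in metadata (default `"a.u."`).
#' @param meta Free-form metadata list (processing history).
#' @return A `meg_epochs` object.
#' @export
meg_epochs <- function(data, times, labels, sfreq, array = NULL,
                       subject = "S01", coil_traces = NULL, eog = NULL,
                       units = "a.u.", meta = list()) {
  e <- structure(list(
    data = data, times = times, labels = factor(labels), sfreq = sfreq,
    array = array,
    channel_ids = if (!is.null(array)) array$channel_ids
                  else sprintf("CH%03d", seq_len(dim(data)[2])),
    subject = subject, coil_traces = coil_traces, eog = eog, units = units,
    meta = meta), class = "meg_epochs")
  validate_epochs(e)
}

#' @export
print.meg_epochs <- function(x, ...) {
  cat(sprintf("MEG epochs [%s]: %d trials x %d channels x %d timepoints @ %g Hz\n",
              x$subject, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  cat(sprintf("  window %.3f..%.3f s; units %s\n", min(x$times), max(x$times),
              x$units))
  print(table(x$labels))
  if (length(x$meta$filters))
    cat("  filters:", paste(x$meta$filters, collapse = " -> "), "\n")
  invisible(x)
}

validate_epochs <- function(e) {
  d <- dim(e$data)
  if (length(d) != 3) stop("'data' must be trials x channels x timepoints",
                           call. = FALSE)
  if (length(e$times) != d[3]) stop("time axis length != data time dimension",
                                    call. = FALSE)
  dt <- diff(e$times)
  if (any(dt <= 0) || max(abs(dt - 1 / e$sfreq)) > 1e-6 / e$sfreq)
    stop("times must increase in steps of 1/sfreq", call. = FALSE)
  if (min(e$times) <= 0 && max(e$times) >= 0 &&
      min(abs(e$times)) > 1e-6 / e$sfreq)
    stop("stimulus onset (t = 0) must fall on a sample", call. = FALSE)
  if (length(e$labels) != d[1]) stop("one label per trial required", call. = FALSE)
  e
}

epoch_times <- function(epoch_window, sfreq) {
  seq.int(round(epoch_window[1] * sfreq), round(epoch_window[2] * sfreq)) / sfreq
}

# spatially smooth random unit-norm topography over the array
random_topography <- function(array, scale, seed, channels = NULL) {
  with_seed(seed, {
    n <- nrow(array$positions)
    K <- exp(-as.matrix(dist(array$positions))^2 / (2 * scale^2))
    topo <- as.vector(chol(K + 1e-8 * diag(n)) %*% rnorm(n))
    if (!is.null(channels)) {
      mask <- rep(0, n)
      mask[resolve_channels(list(channel_ids = array$channel_ids,
                                 array = array), channels)] <- 1
      topo <- topo * mask
    }
    topo / sqrt(sum(topo^2))
  })
}

# 1/f temporal shaping of white noise columns (tp x k matrix)
pink_noise <- function(tp, k, exponent, sfreq) {
  w <- matrix(rnorm(tp * k), tp, k)
  if (exponent == 0) return(w)
  kk <- seq_len(tp) - 1L
  f <- pmin(kk, tp - kk) * sfreq / tp
  g <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(mvfft(mvfft(w) * g, inverse = TRUE)) / tp
  x / sd(x)
}

smoothed_boxcar <- function(times_ms, onset, duration, ramp) {
  up <- pmin(1, pmax(0, (times_ms - onset) / ramp))
  dn <- pmin(1, pmax(0, (onset + duration - times_ms) / ramp))
  up * dn
}

expand_conditions <- function(token, conditions) {
  if (identical(token, "faces")) setdiff(conditions, "scrambled") else token
}

#' Simulate a multi-subject synthetic MEG dataset
#'
#' Generates one epoch set per subject under `cfg` on the given sensor
#' array. Condition means differ only through `cfg$effect_spec` and only
#' from each effect's onset onward; with all effect amplitudes zero the
#' conditions are exchangeable. The same configuration and seed reproduce
#' the output exactly.
#'
#' @param cfg A [simulation_config()].
#' @param array A [make_sensor_array()] result.
#' @return List with one element per subject, each
#'   `list(epochs = meg_epochs, truth = list(...))`; the ground truth
#'   records every injected effect topography and onset and is never
#'   consumed by analysis stages.
#' @export
simulate_dataset <- function(cfg, array) {
  validate_simulation_config(cfg)
  nch <- length(array$channel_ids)
  times <- epoch_times(cfg$epoch_window, cfg$sfreq)
  tms <- times * 1000
  tp <- length(times)
  # condition-independent structure, shared across subjects
  evoked <- matrix(0, nch, tp)
  comp_topo <- list()
  for (ev in cfg$evoked_components) {
    topo <- random_topography(array, cfg$noise$spatial_scale, ev$seed)
    comp_topo[[length(comp_topo) + 1L]] <- topo
    evoked <- evoked + ev$amplitude * outer(topo, exp(-(tms - ev$latency)^2 /
                                                        (2 * ev$width^2)))
  }
  effects <- lapply(seq_along(cfg$effect_spec), function(i) {
    ef <- cfg$effect_spec[[i]]
    topo <- random_topography(array, cfg$noise$spatial_scale,
                              ef$seed %||% derive_seed(cfg$seed, 300 + i),
                              ef$channels %||% NULL)
    list(pair = ef$pair, topo = topo,
         tc = smoothed_boxcar(tms, ef$onset, ef$duration, cfg$ramp_ms),
         amplitude = ef$amplitude, onset = ef$onset)
  })
  Kmix <- NULL
  if (cfg$noise$pink_sd > 0) {
    K <- exp(-as.matrix(dist(array$positions))^2 /
               (2 * cfg$noise$spatial_scale^2))
    Kmix <- chol(K + 1e-8 * diag(nch))
  }
  lapply(seq_len(cfg$n_subjects), function(s) {
    with_seed(derive_seed(cfg$seed, s), {
      simulate_subject(cfg, array, s, times, evoked, effects, Kmix)
    })
  })
}

simulate_subject <- function(cfg, array, s, times, evoked, effects, Kmix) {
  nch <- length(array$channel_ids)
  tp <- length(times)
  ntr <- cfg$n_trials_per_condition * length(cfg$conditions)
  labels <- sample(rep(cfg$conditions, each = cfg$n_trials_per_condition))
  data <- array(0, c(ntr, nch, tp))
  for (tr in seq_len(ntr)) {
    x <- t(evoked)                                   # tp x nch
    if (cfg$noise$pink_sd > 0)
      x <- x + cfg$noise$pink_sd * (pink_noise(tp, nch, cfg$noise$exponent,
                                               cfg$sfreq) %*% Kmix)
    if (cfg$noise$white_sd > 0)
      x <- x + cfg$noise$white_sd * matrix(rnorm(tp * nch), tp, nch)
    data[tr, , ] <- t(x)
  }
  for (ef in effects) {
    a <- expand_conditions(ef$pair[1], cfg$conditions)
    b <- expand_conditions(ef$pair[2], cfg$conditions)
    bump <- ef$amplitude / 2 * outer(ef$topo, ef$tc)   # nch x tp
    for (tr in which(labels %in% a)) data[tr, , ] <- data[tr, , ] + bump
    for (tr in which(labels %in% b)) data[tr, , ] <- data[tr, , ] - bump
  }
  eog <- simulate_eog(cfg, labels, times)
  coils <- simulate_coils(cfg, ntr, tp)
  truth <- list(
    effect_topographies = lapply(effects, `[[`, "topo"),
    effect_pairs = lapply(effects, `[[`, "pair"),
    effect_onsets = vapply(effects, `[[`, numeric(1), "onset"),
    effect_amplitudes = vapply(effects, `[[`, numeric(1), "amplitude"),
    source_location = NULL)
  e <- meg_epochs(data, times, labels, cfg$sfreq, array = array,
                  subject = sprintf("S%02d", s), coil_traces = coils,
                  eog = eog, meta = list(filters = character()))
  list(epochs = e, truth = truth)
}

simulate_eog <- function(cfg, labels, times) {
  ntr <- length(labels); tp <- length(times)
  eog <- array(0, c(ntr, 2, tp))
  dur <- diff(range(times))
  for (tr in seq_len(ntr)) {
    extra <- 0
    if (!is.null(cfg$eog$correlate_pair) &&
        labels[tr] == cfg$eog$correlate_pair[1])
      extra <- cfg$eog$correlate_strength
    nblinks <- rbinom(1, 10, min(1, (cfg$eog$blink_rate + extra) * dur / 10))
    v <- rnorm(tp, sd = 1)
    h <- rnorm(tp, sd = 1)
    if (nblinks > 0) {
      at <- runif(nblinks, min(times), max(times))
      for (b in at) {
        v <- v + cfg$eog$amplitude * exp(-(times - b)^2 / (2 * 0.06^2))
        h <- h + 0.2 * cfg$eog$amplitude * exp(-(times - b)^2 / (2 * 0.06^2))
      }
    }
    eog[tr, 1, ] <- v
    eog[tr, 2, ] <- h
  }
  eog
}

simulate_coils <- function(cfg, ntr, tp) {
  ncs <- max(2L, tp %/% cfg$motion$decimation)
  coils <- array(0, c(ntr, cfg$motion$n_coils, ncs))
  for (tr in seq_len(ntr)) {
    for (co in seq_len(cfg$motion$n_coils)) {
      pos <- matrix(0, ncs, 3)
      for (i in 2:ncs) {
        step <- rnorm(3, sd = cfg$motion$step_sd)
        cand <- pos[i - 1, ] + step
        nc <- sqrt(sum(cand^2))
        if (nc > cfg$motion$max_displacement)
          cand <- cand * cfg$motion$max_displacement / nc
        pos[i, ] <- cand
      }
      coils[tr, co, ] <- sqrt(rowSums(pos^2))
    }
  }
  coils
}

#' Simulate epochs from a current dipole through a forward model
#'
#' Sensor data are the lead field of the chosen source times a shared trial
#' timecourse, plus white noise: the test bed for beamformer localization
#' and virtual-channel reconstruction. A radial dipole in the spherical
#' conductor produces no field and raises a "silent source" error.
#'
#' @param fm A [make_forward_model()] result.
#' @param source_index Grid point index.
#' @param timecourse Numeric source waveform (one value per timepoint).
#' @param orientation Unit 3-vector; default is the orientation maximizing
#'   the lead-field norm (tangential in a spherical conductor).
#' @param n_trials Number of trials.
#' @param noise_sd White sensor noise SD.
#' @param sfreq Sampling rate used to build the time axis (stimulus at 0).
#' @param seed Optional RNG seed.
#' @return `list(epochs = meg_epochs, truth = list(source_location, ...))`.
#' @export
simulate_dipole_dataset <- function(fm, source_index, timecourse,
                                    orientation = NULL, n_trials = 20,
                                    noise_sd = 0.1, sfreq = 600, seed = NULL) {
  L <- fm$leadfield[source_index, , ]              # channels x 3
  if (is.null(orientation)) {
    sv <- svd(L)
    orientation <- sv$v[, 1]
  }
  orientation <- orientation / sqrt(sum(orientation^2))
  l <- as.vector(L %*% orientation)
  if (sqrt(sum(l^2)) < 1e-8 * max(sqrt(sum(L^2)), 1e-300))
    stop("silent source: the requested orientation produces no measurable field",
         call. = FALSE)
  tp <- length(timecourse)
  times <- seq.int(0, tp - 1L) / sfreq
  nch <- length(l)
  with_seed(seed, {
    data <- array(0, c(n_trials, nch, tp))
    clean <- outer(l, timecourse)
    for (tr in seq_len(n_trials))
      data[tr, , ] <- clean + if (noise_sd > 0)
        matrix(rnorm(nch * tp, sd = noise_sd), nch, tp) else 0
    e <- meg_epochs(data, times, rep("dipole", n_trials), sfreq,
                    array = fm$array, subject = "SIM",
                    meta = list(filters = character()))
    list(epochs = e,
         truth = list(source_location = fm$grid[source_index, ],
                      source_index = source_index, orientation = orientation,
                      leadfield = l, timecourse = timecourse))
  })
}
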