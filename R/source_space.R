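# Spherical-conductor forward modeling, LCMV beamforming with vector-norm
# weight normalization and optimal orientation, virtual channels, and
# atlas-ROI peak selection.

# Sarvas field of a unit dipole at r0 inside a sphere centred at the origin,
# evaluated at all sensors and projected on their (radial) orientations.
# Constant physical factors are dropped: lead fields are in arbitrary units.
sarvas_leadfield <- function(r0, positions, orientations) {
  nch <- nrow(positions)
  A <- positions - matrix(r0, nch, 3, byrow = TRUE)
  an <- sqrt(rowSums(A^2))
  rn <- sqrt(rowSums(positions^2))
  ar <- rowSums(A * positions)
  r0r <- as.vector(positions %*% r0)
  Fv <- an * (rn * an + rn^2 - r0r)
  gF <- (an^2 / rn + ar / an + 2 * an + 2 * rn) * positions -
        matrix(an + 2 * rn + ar / an, nch, 3) * matrix(r0, nch, 3, byrow = TRUE)
  L <- matrix(0, nch, 3)
  for (k in 1:3) {
    q <- c(0, 0, 0); q[k] <- 1
    cq <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])          # q x r0
    Bq <- (matrix(Fv, nch, 3) * matrix(cq, nch, 3, byrow = TRUE) -
             matrix(as.vector(positions %*% cq), nch, 3) * gF) / Fv^2
    L[, k] <- rowSums(Bq * orientations)
  }
  L
}

#' Build a spherical-conductor forward model on a volumetric grid
#'
#' Places sources on an isotropic grid (default 6 mm) inside a sphere and
#' computes the magnetic lead field of three orthogonal unit dipoles per
#' source analytically (spherical conductor; radial dipoles are silent).
#' Each source's lead field is pre-reduced to its non-silent subspace
#' (singular vectors with non-negligible gain), which the beamformer uses
#' for orientation optimization.
#'
#' @param array A `sensor_array`.
#' @param grid_resolution Grid step in meters (default 0.006).
#' @param conductor `list(center, radius)` of the conducting sphere
#'   (defaults to a 0.09 m sphere at the origin).
#' @param inner_fraction Sources are kept within this fraction of the
#'   conductor radius (default 0.9).
#' @return A `forward_model`: `grid` (n x 3), `leadfield`
#'   (n x channels x 3), reduced lead fields `L2` and their orientation
#'   bases `V2`, `conductor`, and the `array`.
#' @export
make_forward_model <- function(array, grid_resolution = 0.006,
                               conductor = list(center = c(0, 0, 0),
                                                radius = 0.09),
                               inner_fraction = 0.9) {
  r <- conductor$radius * inner_fraction
  ax <- seq(-r, r, by = grid_resolution)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  grid <- grid[sqrt(rowSums(grid^2)) <= r, , drop = FALSE]
  grid <- grid + matrix(conductor$center, nrow(grid), 3, byrow = TRUE)
  ns <- nrow(grid); nch <- nrow(array$positions)
  pos <- array$positions - matrix(conductor$center, nch, 3, byrow = TRUE)
  lf <- array(0, c(ns, nch, 3))
  L2 <- vector("list", ns); V2 <- vector("list", ns)
  for (i in seq_len(ns)) {
    L <- sarvas_leadfield(grid[i, ] - conductor$center, pos, array$orientations)
    lf[i, , ] <- L
    sv <- svd(L)
    keep <- which(sv$d > 1e-6 * sv$d[1])
    L2[[i]] <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
    V2[[i]] <- sv$v[, keep, drop = FALSE]
  }
  structure(list(grid = grid, leadfield = lf, L2 = L2, V2 = V2,
                 conductor = conductor, resolution = grid_resolution,
                 array = array), class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("Forward model: %d sources at %.0f mm in a %.0f mm sphere, %d channels\n",
              nrow(x$grid), 1000 * x$resolution,
              1000 * x$conductor$radius, dim(x$leadfield)[2]))
  invisible(x)
}

#' Sensor covariance of an epoch set
#'
#' Covariance over all concatenated trial samples, optionally after
#' broadband filtering (default 0.1-100 Hz, clamped below Nyquist with a
#' warning when the sampling rate is too low).
#'
#' @param e A `meg_epochs` object.
#' @param band Bandpass in Hz, or `NULL` to skip filtering.
#' @return Symmetric positive semi-definite covariance matrix (attribute
#'   `"rank_deficient"` set when the spectrum is degenerate, in which case
#'   beamforming must regularize).
#' @export
compute_covariance <- function(e, band = c(0.1, 100)) {
  if (!is.null(band)) {
    nyq <- e$sfreq / 2
    if (band[2] >= nyq) {
      band[2] <- 0.9 * nyq
      warning("covariance band clamped to ", band[2], " Hz (Nyquist limit)")
    }
    e <- apply_filter(e, filter_spec("bandpass", band))
  }
  d <- dim(e$data)
  X <- matrix(aperm(e$data, c(3, 1, 2)), ncol = d[2])  # (tp*trials) x ch
  C <- cov(X)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  rd <- min(ev) < 1e-10 * mean(ev)
  if (rd) warning("covariance is rank-deficient; regularization is mandatory")
  attr(C, "rank_deficient") <- rd
  C
}

#' LCMV beamformer weights with optimal orientation
#'
#' For each source the orientation is chosen to maximize beamformer output
#' power (dominant eigenvector of `(L' C^-1 L)^-1`, equivalently the
#' smallest-eigenvalue direction of `L' C^-1 L` in the source's non-silent
#' subspace); an SNR-optimal variant is available. Unit-gain weights
#' `w = C^-1 l / (l' C^-1 l)` (so `w'l = 1` exactly) are then normalized by
#' their vector norm to mitigate the depth bias; the unnormalized gain is
#' kept for diagnostics.
#'
#' @param fm A `forward_model`.
#' @param C Sensor covariance.
#' @param reg Diagonal loading as a fraction of the mean eigenvalue
#'   (default 0.05).
#' @param orientation `"power"` (default) or `"snr"`.
#' @return A `spatial_filter`: `weights` (sources x channels, unit norm),
#'   `orientation` (sources x 3), `unnormalized_gain`, and `kept` (FALSE
#'   for silent sources, whose weights are `NA`).
#' @export
lcmv_weights <- function(fm, C, reg = 0.05,
                         orientation = c("power", "snr")) {
  orientation <- match.arg(orientation)
  nch <- ncol(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  Creg <- C + reg * mean(ev) * diag(nch)
  Ci <- solve(Creg)
  Ci2 <- Ci %*% Ci
  ns <- nrow(fm$grid)
  W <- matrix(NA_real_, ns, nch)
  ori <- matrix(NA_real_, ns, 3)
  gain <- rep(NA_real_, ns)
  kept <- logical(ns)
  lf_scale <- max(vapply(fm$L2, function(m) sqrt(sum(m^2)), numeric(1)))
  for (i in seq_len(ns)) {
    L2 <- fm$L2[[i]]
    if (sqrt(sum(L2^2)) < 1e-8 * lf_scale) next   # silent source
    M1 <- crossprod(L2, Ci %*% L2)
    eta <- if (orientation == "power") {
      eigen(M1, symmetric = TRUE)$vectors[, ncol(M1)]  # min eigenvalue of M1
    } else {
      M2 <- crossprod(L2, Ci2 %*% L2)
      # maximize (eta' M1 eta) / (eta' M2 eta): generalized eigenproblem
      eg <- eigen(solve(M2, M1))
      Re(eg$vectors[, which.max(Re(eg$values))])
    }
    eta <- eta / sqrt(sum(eta^2))
    l <- as.vector(L2 %*% eta)
    Cil <- as.vector(Ci %*% l)
    w <- Cil / sum(l * Cil)
    g <- sqrt(sum(w^2))
    W[i, ] <- w / g
    gain[i] <- g
    ori[i, ] <- as.vector(fm$V2[[i]] %*% eta)
    kept[i] <- TRUE
  }
  if (any(!kept))
    message(sum(!kept), " silent source(s) excluded from the spatial filter")
  structure(list(weights = W, orientation = ori, unnormalized_gain = gain,
                 kept = kept, reg = reg, fm = fm),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("LCMV spatial filter: %d/%d sources retained, reg = %g\n",
              sum(x$kept), length(x$kept), x$reg))
  invisible(x)
}

#' Project epochs through a spatial filter into virtual channels
#'
#' Each source timecourse is the weighted sum of all sensor signals,
#' `w' x(t)`, per trial. With `normalized = FALSE` the unit-gain weights
#' (before vector-norm normalization) are used, so a noise-free lead-field
#' signal is reconstructed with unit amplitude.
#'
#' @param e A `meg_epochs` object (channels must match the filter).
#' @param filt A `spatial_filter`.
#' @param sources Indices of sources to extract (default all retained).
#' @param normalized Use vector-norm-normalized weights (default `TRUE`).
#' @return A `meg_epochs` object in source space (channel ids `SRC...`,
#'   no sensor array).
#' @export
extract_virtual_channels <- function(e, filt, sources = NULL,
                                     normalized = TRUE) {
  if (ncol(filt$weights) != dim(e$data)[2])
    stop("channel count mismatch between epochs and filter", call. = FALSE)
  if (is.null(sources)) sources <- which(filt$kept)
  W <- filt$weights[sources, , drop = FALSE]
  if (!normalized) W <- W * filt$unnormalized_gain[sources]
  d <- dim(e$data)
  out <- array(0, c(d[1], length(sources), d[3]))
  for (tr in seq_len(d[1]))
    out[tr, , ] <- W %*% matrix(e$data[tr, , ], d[2], d[3])
  e$data <- out
  e$array <- NULL
  e$channel_ids <- sprintf("SRC%05d", sources)
  e$meta$space <- "source"
  e$meta$sources <- sources
  e$coil_traces <- NULL
  e
}

#' Synthetic volumetric ROI atlas over a source grid
#'
#' Partitions the forward-model grid into `n_rois` compact regions by
#' k-means on source coordinates — a stand-in, AAL-like parcellation (84
#' regions by default) for tests and demonstrations that must run without
#' external atlas files.
#'
#' @param fm A `forward_model`.
#' @param n_rois Number of regions (default 84).
#' @param seed RNG seed for the clustering.
#' @return An `roi_atlas`: integer `labels` per grid point, region `names`,
#'   and the grid.
#' @export
make_synthetic_atlas <- function(fm, n_rois = 84, seed = 1) {
  if (nrow(fm$grid) < n_rois)
    stop("fewer grid points than requested ROIs", call. = FALSE)
  km <- with_seed(seed, kmeans(fm$grid, centers = n_rois, iter.max = 100,
                               nstart = 3))
  structure(list(labels = km$cluster,
                 names = sprintf("ROI_%03d", seq_len(n_rois)),
                 grid = fm$grid), class = "roi_atlas")
}

#' Write an atlas as NIfTI + TSV label lookup
#'
#' Voxelizes the grid labels into a volume at the forward-model resolution
#' and writes the id-to-name lookup as TSV.
#'
#' @param atlas An `roi_atlas`.
#' @param fm The `forward_model` the atlas lives on.
#' @param nii_path,tsv_path Output paths.
#' @return Invisibly, `nii_path`.
#' @export
write_atlas_nifti <- function(atlas, fm, nii_path, tsv_path) {
  res <- fm$resolution
  mn <- apply(fm$grid, 2, min)
  ijk <- round(sweep(fm$grid, 2, mn) / res) + 1
  dims <- apply(ijk, 2, max)
  vol <- array(0L, dims)
  vol[ijk] <- atlas$labels
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(res * 1000, 3)   # mm
  RNifti::writeNifti(img, nii_path)
  write.table(data.frame(id = seq_along(atlas$names), name = atlas$names),
              tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(nii_path)
}

#' Read a volumetric atlas (NIfTI + TSV) onto a forward-model grid
#'
#' Maps every grid point to the label of its nearest voxel. Grid points
#' falling outside the labelled volume cause a registration error.
#'
#' @param nii_path,tsv_path Atlas volume and label lookup.
#' @param fm The target `forward_model`.
#' @return An `roi_atlas`.
#' @export
read_atlas <- function(nii_path, tsv_path, fm) {
  vol <- RNifti::readNifti(nii_path)
  lut <- read.table(tsv_path, header = TRUE, sep = "\t")
  res <- RNifti::pixdim(vol)[1] / 1000
  mn <- apply(fm$grid, 2, min)
  ijk <- round(sweep(fm$grid, 2, mn) / res) + 1
  if (any(ijk < 1) || any(sweep(ijk, 2, dim(vol)) > 0))
    stop("atlas/grid registration mismatch: grid points outside the volume",
         call. = FALSE)
  labels <- vol[ijk]
  structure(list(labels = as.integer(labels),
                 names = as.character(lut$name[order(lut$id)]),
                 grid = fm$grid), class = "roi_atlas")
}

# band-limited sensor covariance from Hanning-tapered trial spectra; used
# for spectral peak selection (scale factors irrelevant for the argmax)
banded_csd <- function(e, band) {
  d <- dim(e$data)
  tp <- d[3]
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(tp) / (tp + 1))
  f <- (seq_len(tp) - 1) * e$sfreq / tp
  keep <- which(f >= band[1] & f <= min(band[2], e$sfreq / 2))
  Cb <- matrix(0, d[2], d[2])
  for (tr in seq_len(d[1])) {
    X <- t(matrix(e$data[tr, , ], d[2], tp)) * taper   # tp x ch
    Fx <- mvfft(X)[keep, , drop = FALSE]
    Cb <- Cb + Re(crossprod(Conj(Fx), Fx))
  }
  Cb / (d[1] * tp * sum(taper^2))
}

#' Select the spectral-peak virtual channel of each atlas ROI
#'
#' Estimates every source's integrated band power (Hanning-tapered spectra,
#' default 1-100 Hz) through the spatial filter and keeps, per ROI, the grid
#' point with maximal power (ties broken deterministically by lowest grid
#' index). Empty ROIs are dropped with a warning.
#'
#' @param e Sensor-space `meg_epochs` (all conditions).
#' @param filt A `spatial_filter` on the atlas grid.
#' @param atlas An `roi_atlas`.
#' @param band Integration band in Hz.
#' @return A `virtual_channel_set`: `roi_names`, `peak_index` (grid index
#'   per ROI) and per-source `power`; feed it to
#'   [extract_roi_timecourses()].
#' @export
pick_roi_peaks <- function(e, filt, atlas, band = c(1, 100)) {
  if (nrow(filt$weights) != length(atlas$labels))
    stop("filter and atlas live on different grids", call. = FALSE)
  Cb <- banded_csd(e, band)
  W <- filt$weights
  power <- rep(NA_real_, nrow(W))
  ok <- filt$kept
  power[ok] <- rowSums((W[ok, , drop = FALSE] %*% Cb) * W[ok, , drop = FALSE])
  peak <- integer(0); nm <- character(0)
  for (r in seq_along(atlas$names)) {
    idx <- which(atlas$labels == r & ok)
    if (!length(idx)) {
      warning("ROI '", atlas$names[r], "' contains no usable source; dropped")
      next
    }
    peak <- c(peak, idx[which.max(power[idx])])   # which.max: lowest index wins
    nm <- c(nm, atlas$names[r])
  }
  structure(list(roi_names = nm, peak_index = peak, power = power,
                 band = band), class = "virtual_channel_set")
}

#' Extract ROI-peak virtual-channel epochs
#'
#' @param e Sensor-space `meg_epochs`.
#' @param filt A `spatial_filter`.
#' @param vcs A `virtual_channel_set` from [pick_roi_peaks()].
#' @return Source-space `meg_epochs` with one channel per ROI (named by
#'   ROI).
#' @export
extract_roi_timecourses <- function(e, filt, vcs) {
  out <- extract_virtual_channels(e, filt, sources = vcs$peak_index)
  out$channel_ids <- vcs$roi_names
  out
}
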