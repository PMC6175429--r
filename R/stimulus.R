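# Stimulus-set equalization in the Fourier amplitude domain, phase-scrambled
# noise images, GIST spatial-envelope descriptors, and image-level control
# classification with permutation tests.

#' Construct a stimulus set
#'
#' @param images List of grayscale matrices with intensities in `[0, 1]`;
#'   all images must share dimensions.
#' @param condition Label per image.
#' @param ids Image identifiers (default `img_001`, ...).
#' @return A `stimulus_set`.
#' @export
stimulus_set <- function(images, condition, ids = NULL) {
  stopifnot(is.list(images), length(images) == length(condition))
  dims <- vapply(images, dim, numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must share dimensions", call. = FALSE)
  rng <- range(unlist(lapply(images, range)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("intensities must lie in [0, 1]; normalize first", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  structure(list(images = images, condition = as.character(condition),
                 ids = ids, dim = dims[, 1]), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d images of %d x %d px\n", length(x$images),
              x$dim[1], x$dim[2]))
  print(table(x$condition))
  invisible(x)
}

#' Read grayscale PNG images into a stimulus set
#'
#' Color images are converted to grayscale by channel averaging; intensities
#' are left on the PNG scale `[0, 1]`.
#'
#' @param paths PNG file paths.
#' @param condition Label per image.
#' @return A `stimulus_set`.
#' @export
read_stimuli <- function(paths, condition) {
  imgs <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3) im <- apply(im[, , 1:min(3, dim(im)[3])], c(1, 2), mean)
    im
  })
  stimulus_set(imgs, condition, ids = basename(paths))
}

#' Write a stimulus set as grayscale PNGs
#' @param s A `stimulus_set`.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_stimuli <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(sub("\\.png$", "", s$ids), ".png"))
  for (i in seq_along(s$images))
    png::writePNG(pmin(1, pmax(0, s$images[[i]])), paths[i])
  invisible(paths)
}

mean_amplitude_spectrum <- function(images) {
  amps <- lapply(images, function(im) Mod(fft(im)))
  Reduce(`+`, amps) / length(amps)
}

#' Equalize the Fourier amplitude spectra of a stimulus set
#'
#' Every image's 2D Fourier amplitude spectrum is replaced by the average
#' spectrum across the set, keeping the image's own phases, and the inverse
#' transform is returned. Output values are real but may leave `[0, 1]`;
#' with `clip = TRUE` they are clipped back and the clipped fraction is
#' reported as an attribute.
#'
#' @param s A `stimulus_set` with at least 2 images.
#' @param clip Clip outputs to `[0, 1]` (default `FALSE`).
#' @return A `stimulus_set` whose images all share the mean amplitude
#'   spectrum (attribute `"mean_amplitude"`; attribute `"clipped_fraction"`
#'   when clipping).
#' @export
equalize_amplitude_spectra <- function(s, clip = FALSE) {
  if (length(s$images) < 2) stop("need at least 2 images", call. = FALSE)
  n <- prod(s$dim)
  amp <- mean_amplitude_spectrum(s$images)
  out <- lapply(s$images, function(im) {
    ph <- Arg(fft(im))
    Re(fft(amp * exp(1i * ph), inverse = TRUE)) / n
  })
  cf <- NA_real_
  if (clip) {
    tot <- sum(vapply(out, function(im) sum(im < 0 | im > 1), numeric(1)))
    cf <- tot / (n * length(out))
    out <- lapply(out, function(im) pmin(1, pmax(0, im)))
  }
  res <- structure(list(images = out, condition = s$condition, ids = s$ids,
                        dim = s$dim), class = "stimulus_set")
  attr(res, "mean_amplitude") <- amp
  if (clip) attr(res, "clipped_fraction") <- cf
  res
}

#' Phase-scrambled noise images from a stimulus set
#'
#' Combines the set's mean Fourier amplitude spectrum with random phases.
#' Phases are taken from the transform of white noise, which makes them
#' Hermitian-symmetric by construction (DC and Nyquist bins get phase 0 or
#' pi), so the inverse transform is exactly real.
#'
#' @param s A `stimulus_set` (or the output of
#'   [equalize_amplitude_spectra()]).
#' @param n Number of scrambled images.
#' @param seed Optional RNG seed.
#' @return A `stimulus_set` of `n` real-valued noise images labelled
#'   `"scrambled"` (not clipped; values can leave `[0, 1]`).
#' @export
make_scrambled <- function(s, n, seed = NULL) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  amp <- attr(s, "mean_amplitude") %||% mean_amplitude_spectrum(s$images)
  np <- prod(s$dim)
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      ph <- Arg(fft(matrix(rnorm(np), s$dim[1], s$dim[2])))
      Re(fft(amp * exp(1i * ph), inverse = TRUE)) / np
    })
    structure(list(images = out, condition = rep("scrambled", n),
                   ids = sprintf("scrambled_%03d", seq_len(n)), dim = s$dim),
              class = "stimulus_set")
  })
}

# one-sided log-Gabor transfer functions on the unshifted frequency grid
gabor_bank <- function(h, w, n_scales, n_orientations) {
  fy <- (seq_len(h) - 1) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(w) - 1) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  f <- sqrt(FX^2 + FY^2)
  theta <- atan2(FY, FX)
  half <- FX > 0 | (FX == 0 & FY > 0)    # analytic (one-sided) response
  sig_f <- log(2) / 2                    # ~1 octave radial bandwidth
  bank <- list()
  for (sc in seq_len(n_scales)) {
    f0 <- 0.25 / 2^(sc - 1)
    radial <- ifelse(f > 0, exp(-(log(pmax(f, 1e-12) / f0))^2 / (2 * sig_f^2)), 0)
    for (o in seq_len(n_orientations)) {
      th0 <- (o - 1) * pi / n_orientations
      dth <- atan2(sin(theta - th0), cos(theta - th0))
      dth <- pmin(abs(dth), abs(pi - abs(dth)))  # orientation is mod pi
      ang <- exp(-dth^2 / (2 * (pi / (2 * n_orientations))^2))
      bank[[length(bank) + 1L]] <- radial * ang * half
    }
  }
  bank
}

#' GIST spatial-envelope descriptor of an image
#'
#' Applies a bank of oriented band-pass (log-Gabor) filters at several
#' scales and orientations and averages the filter energy within each cell
#' of a coarse spatial grid; the result is a holistic representation of the
#' image's spatial envelope. With the default 4 scales x 4 orientations x
#' 4 x 4 grid the descriptor has 256 values.
#'
#' @param image Grayscale matrix.
#' @param n_scales,n_orientations,grid Bank configuration.
#' @param prefilter Apply local contrast normalization first (default
#'   `FALSE`).
#' @return Numeric vector of length
#'   `n_scales * n_orientations * grid^2`, ordered scale-major, then
#'   orientation, then grid cell.
#' @export
gist_descriptor <- function(image, n_scales = 4, n_orientations = 4, grid = 4,
                            prefilter = FALSE) {
  h <- nrow(image); w <- ncol(image)
  if (h < 2^n_scales || w < 2^n_scales || h < grid || w < grid)
    stop("image smaller than the filter support / grid", call. = FALSE)
  if (prefilter) {
    k <- max(3L, round(min(h, w) / 16)); if (k %% 2 == 0) k <- k + 1L
    box <- function(m) {
      f <- rep(1 / k, k)
      t(apply(apply(m, 2, function(v) stats::filter(v, f, circular = TRUE)),
              1, function(v) stats::filter(v, f, circular = TRUE)))
    }
    mu <- box(image)
    image <- (image - mu) / (sqrt(pmax(box((image - mu)^2), 0)) + 0.02)
  }
  Fimg <- fft(image)
  bank <- gabor_bank(h, w, n_scales, n_orientations)
  ry <- ceiling(seq_len(h) / h * grid)
  rx <- ceiling(seq_len(w) / w * grid)
  cell <- (matrix(ry, h, w) - 1) * grid + matrix(rx, h, w, byrow = TRUE)
  out <- numeric(0)
  for (G in bank) {
    resp <- fft(Fimg * G, inverse = TRUE) / (h * w)
    energy <- Mod(resp)^2
    means <- vapply(seq_len(grid^2), function(cl) mean(energy[cell == cl]),
                    numeric(1))
    out <- c(out, means)
  }
  out
}

#' Image-level control classification
#'
#' Tests whether two stimulus conditions are separable from low-level image
#' properties alone: pixel intensities or GIST descriptors are fed to a
#' linear SVM evaluated by leave-one-out cross-validation (or
#' resubstitution), with a permutation p-value from label shuffles.
#'
#' High-dimensional pixel features are first reduced by thin SVD to the
#' span of the images, which leaves every decision function unchanged.
#'
#' @param s A `stimulus_set`.
#' @param features `"pixels"` or `"gist"`.
#' @param pair Two condition labels.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @param cv `"loo"` (default) or `"resub"`.
#' @param cost SVM box constraint.
#' @param ... Passed to [gist_descriptor()].
#' @return List `accuracy`, `p`, `null_accuracy`, `n_images`.
#' @export
image_level_classification <- function(s, features = c("pixels", "gist"),
                                       pair, n_perm = 999, seed = NULL,
                                       cv = c("loo", "resub"), cost = 1, ...) {
  features <- match.arg(features)
  cv <- match.arg(cv)
  keep <- which(s$condition %in% pair)
  y <- factor(s$condition[keep], levels = sort(pair))
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 images in each of the two conditions", call. = FALSE)
  X <- if (features == "pixels")
    do.call(rbind, lapply(s$images[keep], as.vector))
  else
    do.call(rbind, lapply(s$images[keep], gist_descriptor, ...))
  if (ncol(X) > nrow(X)) {     # rotate into the span of the images
    sv <- svd(scale(X, scale = FALSE), nu = nrow(X), nv = 0)
    X <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))])
  }
  acc_fun <- function(yy) {
    yy <- as.character(yy)
    if (cv == "resub") {
      fit <- fit_svm(X, yy, cost = cost)
      mean(predict(fit, X) == yy)
    } else {
      correct <- vapply(seq_len(nrow(X)), function(i) {
        fit <- fit_svm(X[-i, , drop = FALSE], yy[-i], cost = cost)
        predict(fit, X[i, , drop = FALSE]) == yy[i]
      }, logical(1))
      mean(correct)
    }
  }
  pn <- label_shuffle_null(acc_fun, y, n_perm = n_perm, seed = seed)
  list(accuracy = pn$observed, p = pn$p, null_accuracy = pn$null_values,
       n_images = length(keep))
}
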