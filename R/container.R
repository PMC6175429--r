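# Epoch container: a documented directory layout mirroring an HDF5-style
# schema (/data /times /labels /channels /coils /eog /meta), with arrays as
# flat little-endian float64 files and metadata as JSON.

#' Write epochs to the package's on-disk container
#'
#' The layout holds `meta.json` (dimensions, time axis, labels, channel ids
#' and positions, sampling rate, units, processing history) plus flat
#' binary float64 arrays `data.bin`, and optionally `coils.bin` and
#' `eog.bin`, in column-major order of their recorded dimensions.
#'
#' @param e A `meg_epochs` object.
#' @param path Directory to create/overwrite.
#' @return Invisibly, `path`.
#' @export
write_epochs <- function(e, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema = "megmvpa-epochs-v1",
    dims = dim(e$data), times = e$times, labels = as.character(e$labels),
    label_levels = levels(e$labels), sfreq = e$sfreq, subject = e$subject,
    units = e$units, channel_ids = e$channel_ids, meta = e$meta,
    coil_dims = if (!is.null(e$coil_traces)) dim(e$coil_traces),
    eog_dims = if (!is.null(e$eog)) dim(e$eog),
    array = if (!is.null(e$array)) list(
      channel_ids = e$array$channel_ids,
      positions = as.vector(e$array$positions),
      orientations = as.vector(e$array$orientations),
      neighbors = e$array$neighbors,
      groups = as.character(e$array$groups),
      radius = e$array$radius, threshold = e$array$threshold,
      layout = e$array$layout))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  wb <- function(x, f) {
    con <- file(file.path(path, f), "wb")
    on.exit(close(con))
    writeBin(as.vector(x), con, size = 8, endian = "little")
  }
  wb(e$data, "data.bin")
  if (!is.null(e$coil_traces)) wb(e$coil_traces, "coils.bin")
  if (!is.null(e$eog)) wb(e$eog, "eog.bin")
  invisible(path)
}

#' Read epochs from the on-disk container
#'
#' @param path Directory written by [write_epochs()].
#' @return A `meg_epochs` object equal to the one written.
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    stop("not a megmvpa epoch container (no meta.json): ", path, call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$schema, "megmvpa-epochs-v1"))
    stop("not a megmvpa epoch container: ", path, call. = FALSE)
  rb <- function(f, dims) {
    con <- file(file.path(path, f), "rb")
    on.exit(close(con))
    array(readBin(con, "double", prod(dims), size = 8, endian = "little"),
          dims)
  }
  arr <- NULL
  if (!is.null(meta$array)) {
    a <- meta$array
    n <- length(a$channel_ids)
    arr <- structure(list(
      channel_ids = a$channel_ids,
      positions = matrix(a$positions, n, 3,
                         dimnames = list(a$channel_ids, NULL)),
      orientations = matrix(a$orientations, n, 3),
      neighbors = if (is.matrix(a$neighbors))
        lapply(seq_len(nrow(a$neighbors)), function(i)
          as.integer(a$neighbors[i, ]))
      else lapply(a$neighbors, as.integer),
      groups = factor(a$groups, levels = c("occipital", "temporal",
                                           "parietal", "frontocentral")),
      radius = a$radius, threshold = a$threshold, layout = a$layout),
      class = "sensor_array")
  }
  e <- meg_epochs(
    data = rb("data.bin", meta$dims),
    times = meta$times,
    labels = factor(meta$labels, levels = meta$label_levels),
    sfreq = meta$sfreq, array = arr, subject = meta$subject,
    coil_traces = if (!is.null(meta$coil_dims)) rb("coils.bin", meta$coil_dims),
    eog = if (!is.null(meta$eog_dims)) rb("eog.bin", meta$eog_dims),
    units = meta$units,
    meta = lapply(meta$meta, function(x) x))
  e
}
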