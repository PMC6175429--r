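# Scalp-like sensor geometries with neighbor graphs and anatomical groups.

#' Construct a sensor array
#'
#' Places `n_channels` radial sensors on a spherical cap (a stand-in for a
#' whole-head axial gradiometer layout) or on a ring, builds a symmetric
#' distance-threshold neighbor graph, and assigns each channel to one
#' anatomical group by angular position: superior sensors are parietal,
#' anterior ones frontocentral, posterior ones occipital and lateral ones
#' temporal.
#'
#' When `neighbor_threshold` is `NULL` the threshold is tuned so that
#' neighbor counts fall inside `neighbor_range` (the 4-10 sensor searchlight
#' band of whole-head gradiometer templates) whenever some threshold
#' achieves it.
#'
#' @param n_channels Number of channels (>= 8 for the cap layout; the ring
#'   accepts >= 3).
#' @param layout `"sphere-cap"` (default) or `"ring"`.
#' @param neighbor_threshold Distance threshold in meters, or `NULL` to tune.
#' @param neighbor_range Target `[min, max]` neighbor counts for tuning.
#' @param radius Sensor shell radius in meters (default 0.102).
#' @param cap_angle Polar half-angle of the cap in degrees (default 120).
#' @return A `sensor_array`: `channel_ids`, `positions` (n x 3, meters),
#'   `orientations` (unit radial normals), `neighbors` (list of integer
#'   vectors), `groups` (factor) and the `threshold` used.
#' @export
make_sensor_array <- function(n_channels, layout = c("sphere-cap", "ring"),
                              neighbor_threshold = NULL,
                              neighbor_range = c(4, 10), radius = 0.102,
                              cap_angle = 120) {
  layout <- match.arg(layout)
  if (layout == "sphere-cap" && n_channels < 8)
    stop("'n_channels' must be >= 8 for the sphere-cap layout", call. = FALSE)
  if (layout == "ring" && n_channels < 3)
    stop("'n_channels' must be >= 3 for the ring layout", call. = FALSE)
  pos <- if (layout == "sphere-cap") {
    # Fibonacci lattice restricted to the cap; z up, y anterior, x right
    i <- seq_len(n_channels) - 0.5
    costh <- 1 - (1 - cos(cap_angle * pi / 180)) * i / n_channels
    th <- acos(costh)
    ph <- i * pi * (3 - sqrt(5))
    radius * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  } else {
    ph <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
    radius * cbind(cos(ph), sin(ph), 0)
  }
  d <- as.matrix(dist(pos))
  if (min(d[upper.tri(d)]) < 1e-9)
    stop("degenerate layout: coincident sensor positions", call. = FALSE)
  if (is.null(neighbor_threshold))
    neighbor_threshold <- tune_neighbor_threshold(d, neighbor_range)
  adj <- d > 0 & d <= neighbor_threshold
  neighbors <- lapply(seq_len(n_channels), function(i) unname(which(adj[i, ])))
  th_deg <- acos(pmin(1, pos[, 3] / radius)) * 180 / pi
  az <- atan2(pos[, 2], pos[, 1]) * 180 / pi    # 90 = anterior, -90 = posterior
  grp <- ifelse(th_deg < 40, "parietal",
         ifelse(az > 45 & az < 135, "frontocentral",
         ifelse(az < -45 & az > -135, "occipital", "temporal")))
  ids <- sprintf("MEG%03d", seq_len(n_channels))
  rownames(pos) <- ids
  structure(list(
    channel_ids = ids, positions = pos, orientations = pos / radius,
    neighbors = neighbors,
    groups = factor(grp, levels = c("occipital", "temporal", "parietal",
                                    "frontocentral")),
    radius = radius, threshold = neighbor_threshold, layout = layout),
    class = "sensor_array")
}

# choose the distance threshold whose neighbor-count histogram best fits the
# requested band; exact fit preferred, otherwise minimal violation
tune_neighbor_threshold <- function(d, range) {
  cand <- sort(unique(d[upper.tri(d)]))
  cand <- cand[cand > 0] * (1 + 1e-9)
  best <- cand[1]; best_pen <- Inf
  for (th in cand) {
    counts <- rowSums(d > 0 & d <= th)
    pen <- sum(pmax(0, range[1] - counts)) + sum(pmax(0, counts - range[2]))
    if (pen < best_pen) { best_pen <- pen; best <- th }
    if (pen == 0) break
    if (min(counts) > range[2]) break
  }
  if (best_pen > 0)
    warning("no threshold puts all neighbor counts inside [",
            range[1], ", ", range[2], "]; closest used")
  best
}

#' @export
print.sensor_array <- function(x, ...) {
  counts <- lengths(x$neighbors)
  cat(sprintf("Sensor array (%s): %d channels, radius %.3f m\n",
              x$layout, length(x$channel_ids), x$radius))
  cat(sprintf("  neighbors per channel: %d-%d (mean %.2f), threshold %.1f mm\n",
              min(counts), max(counts), mean(counts), 1000 * x$threshold))
  print(table(x$groups))
  invisible(x)
}
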