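# Dependent variables derived from aligned pose tracks: locomotion and
# nose-motion distance, lever-zone entrances, entrances per meter, and
# occupancy grids.

moving_average <- function(v, window) {
  n <- length(v)
  w <- as.integer(window)
  if (w < 1L) pl_stop("window must be >= 1", "prelever_parameter_error")
  if (w > n) pl_stop("window exceeds series length",
                     "prelever_parameter_error")
  if (w == 1L) return(v)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  i <- seq_len(n)
  lo <- i - left
  hi <- i + right
  # where the centered window would spill past an edge, shrink both sides
  # equally so the average stays centered on the point
  edge <- lo < 1L | hi > n
  h <- pmin(i - 1L, n - i)
  lo[edge] <- (i - h)[edge]
  hi[edge] <- (i + h)[edge]
  cs <- cumsum(c(0, v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a node's position series
#'
#' Centered moving average of x and y independently, the standard jitter
#' suppression applied before path-length accumulation (frame-to-frame
#' keypoint jitter otherwise inflates distance traveled). The window is
#' truncated symmetrically at the series edges so endpoints average over
#' however many frames fit.
#'
#' @param track A [pose_track()] or an n-by-2 numeric matrix of positions.
#' @param node Node label (ignored when `track` is already a matrix).
#' @param window Window width in frames; default 10.
#' @return An n-by-2 matrix of smoothed positions.
#' @export
smooth_positions <- function(track, node = NULL, window = 10) {
  xy <- if (inherits(track, "pose_track")) node_positions(track, node)
        else as.matrix(track)
  cbind(x = moving_average(xy[, 1], window),
        y = moving_average(xy[, 2], window))
}

#' Total Euclidean path length in meters
#'
#' Sum of frame-to-frame Euclidean steps in pixels, converted to meters
#' through the calibration factor. Applied to the catheter node this is
#' locomotion; applied to the nose it is nose motion.
#'
#' @param positions n-by-2 matrix of (x, y) pixel positions (finite).
#' @param cm_per_px Calibration scalar from [compute_cm_per_px()].
#' @return Distance in meters (0 for a single frame).
#' @export
path_length <- function(positions, cm_per_px) {
  xy <- as.matrix(positions)
  if (nrow(xy) < 1L || any(!is.finite(xy))) {
    pl_stop("positions must be non-empty and finite (interpolate first)",
            "prelever_contract_error")
  }
  if (nrow(xy) == 1L) return(0)
  steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  sum(steps) * cm_per_px / 100
}

#' Axis-aligned lever zone
#'
#' @param center Numeric length-2 (x, y) pixel center.
#' @param half_x,half_y Positive half-extents in pixels; defaults 30 and 18,
#'   the zone the entrance metrics are defined on.
#' @return A `zone_box`.
#' @export
zone_box <- function(center, half_x = 30, half_y = 18) {
  if (!is_scalar_number(half_x) || !is_scalar_number(half_y) ||
      half_x <= 0 || half_y <= 0) {
    pl_stop("zone half-extents must be positive", "prelever_parameter_error")
  }
  structure(list(center = as.numeric(center), half_x = half_x,
                 half_y = half_y),
            class = "zone_box")
}

#' @export
print.zone_box <- function(x, ...) {
  cat(sprintf("<zone_box> center (%.1f, %.1f), x ±%g, y ±%g px\n",
              x$center[1], x$center[2], x$half_x, x$half_y))
  invisible(x)
}

#' Build the lever zone from tracked lever coordinates
#'
#' The lever is physically static, so its per-frame keypoint scatter is
#' tracking jitter; the zone centers on the per-axis median of the observed
#' coordinates, which resists that jitter.
#'
#' @param track A [pose_track()].
#' @param lever_node Label of the lever node (`"active_lever"` or
#'   `"inactive_lever"`).
#' @param half_x,half_y Zone half-extents in pixels (defaults 30, 18).
#' @return A [zone_box()].
#' @export
make_lever_zone <- function(track, lever_node, half_x = 30, half_y = 18) {
  xy <- node_positions(track, lever_node)
  ok <- is.finite(xy[, 1]) & is.finite(xy[, 2])
  if (!any(ok)) {
    pl_stop(paste0("lever node ", lever_node, " was never observed"),
            "prelever_zone_error")
  }
  zone_box(c(median(xy[ok, 1]), median(xy[ok, 2])), half_x, half_y)
}

#' Zone membership per frame
#'
#' Membership is inclusive of the boundary, giving deterministic behavior
#' on integer pixel coordinates.
#'
#' @param positions n-by-2 position matrix.
#' @param box A [zone_box()].
#' @return Logical vector, one element per frame.
#' @export
in_zone <- function(positions, box) {
  xy <- as.matrix(positions)
  abs(xy[, 1] - box$center[1]) <= box$half_x &
    abs(xy[, 2] - box$center[2]) <= box$half_y
}

#' Count nose entrances into a lever zone
#'
#' An entrance is an outside-to-inside transition between consecutive
#' frames. A series that starts inside contributes nothing until it first
#' exits and re-enters: entrances are events, and the pre-lever segment
#' begins mid-exploration.
#'
#' @param positions n-by-2 nose position matrix.
#' @param box A [zone_box()].
#' @return Non-negative integer entrance count.
#' @export
count_zone_entrances <- function(positions, box) {
  inside <- in_zone(positions, box)
  n <- length(inside)
  if (n < 2L) return(0L)
  sum(inside[-1L] & !inside[-n])
}

#' Entrances normalized by distance traveled
#'
#' Seeking corrected for general activity. Below `eps` meters of locomotion
#' the rate is numerically meaningless and is returned as `NA` — an
#' explicit undefined marker that downstream summaries exclude rather than
#' zero out.
#'
#' @param count Entrance count (>= 0).
#' @param locomotion_m Distance traveled in meters (>= 0).
#' @param eps Guard threshold in meters (default 0.01).
#' @return Entrances per meter, or `NA_real_` when undefined.
#' @export
entrances_per_meter <- function(count, locomotion_m, eps = 0.01) {
  stopifnot(count >= 0, locomotion_m >= 0)
  if (!is.finite(locomotion_m) || locomotion_m < eps) return(NA_real_)
  count / locomotion_m
}

#' Occupancy heatmap of a position series
#'
#' 2-D histogram of nose coordinates over a chamber rectangle. Positions
#' outside the bounds are clipped onto the boundary and tallied (their count
#' is reported in `n_clipped`), so the grid always conserves the frame
#' count. Grids with identical bin edges add bin-wise via `+`, the overlay
#' semantics used for per-block session composites.
#'
#' @param positions n-by-2 position matrix (finite).
#' @param bins Length-2 integer vector: bins in x and y.
#' @param bounds Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @return An `occupancy_grid`: list with `counts` (nx-by-ny matrix),
#'   `xedges`, `yedges`, `n_frames`, `n_clipped`.
#' @export
occupancy_heatmap <- function(positions, bins = c(27L, 16L),
                              bounds = c(xmin = 0, xmax = 270,
                                         ymin = 0, ymax = 162)) {
  if (any(bins < 1L)) {
    pl_stop("bins must be positive", "prelever_parameter_error")
  }
  xy <- as.matrix(positions)
  if (any(!is.finite(xy))) {
    pl_stop("positions must be finite", "prelever_contract_error")
  }
  b <- as.numeric(bounds[c("xmin", "xmax", "ymin", "ymax")])
  clipped <- xy[, 1] < b[1] | xy[, 1] > b[2] |
             xy[, 2] < b[3] | xy[, 2] > b[4]
  x <- pmin(pmax(xy[, 1], b[1]), b[2])
  y <- pmin(pmax(xy[, 2], b[3]), b[4])
  xedges <- seq(b[1], b[2], length.out = bins[1] + 1L)
  yedges <- seq(b[3], b[4], length.out = bins[2] + 1L)
  ix <- pmin(pmax(findInterval(x, xedges, rightmost.closed = TRUE), 1L),
             bins[1])
  iy <- pmin(pmax(findInterval(y, yedges, rightmost.closed = TRUE), 1L),
             bins[2])
  counts <- matrix(0L, bins[1], bins[2])
  tab <- table(factor(ix, levels = seq_len(bins[1])),
               factor(iy, levels = seq_len(bins[2])))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, xedges = xedges, yedges = yedges,
                 n_frames = nrow(xy), n_clipped = sum(clipped)),
            class = "occupancy_grid")
}

#' @export
`+.occupancy_grid` <- function(e1, e2) {
  if (!isTRUE(all.equal(e1$xedges, e2$xedges)) ||
      !isTRUE(all.equal(e1$yedges, e2$yedges))) {
    pl_stop("occupancy grids have different bin edges",
            "prelever_parameter_error")
  }
  structure(list(counts = e1$counts + e2$counts, xedges = e1$xedges,
                 yedges = e1$yedges,
                 n_frames = e1$n_frames + e2$n_frames,
                 n_clipped = e1$n_clipped + e2$n_clipped),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("<occupancy_grid> ", nrow(x$counts), "x", ncol(x$counts),
      " bins, ", x$n_frames, " frames (", x$n_clipped, " clipped)\n",
      sep = "")
  invisible(x)
}

#' Write an occupancy grid and its geometry sidecar
#'
#' The grid goes to `path` as a delimited matrix (rows = x bins); bin edges
#' and any zone boxes go to `<path>.meta.yaml` for plotting. For display the
#' y axis should be flipped: video coordinates put the origin top-left.
#'
#' @param grid An `occupancy_grid`.
#' @param path Output path for the counts matrix.
#' @param zones Optional named list of [zone_box()] annotations.
#' @return `path`, invisibly.
#' @export
write_occupancy_grid <- function(grid, path, zones = list()) {
  write.table(grid$counts, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  meta <- list(
    xedges = as.numeric(grid$xedges), yedges = as.numeric(grid$yedges),
    n_frames = grid$n_frames, n_clipped = grid$n_clipped,
    zones = lapply(zones, function(z) {
      list(center = as.numeric(z$center), half_x = z$half_x,
           half_y = z$half_y)
    })
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
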