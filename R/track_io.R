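# Reading, validating, repairing, calibrating, and aligning pose-track
# recordings. A track file is delimited text with one row per video frame:
# a `frame` column (contiguous integers from 0) followed by `<node>.x` and
# `<node>.y` pixel columns for every tracked node. Missing detections are
# empty fields, never zeros.

#' Default thirteen-node skeleton
#'
#' The full keypoint set tracked on each rat: nose, both ears, neck, four
#' paws, tail base, the back-mounted catheter port, plus the static chamber
#' nodes (both levers and the cue light). The catheter is the anchor: it is
#' the most reliably tracked point and serves as the locomotion proxy.
#'
#' @return A `node_set`.
#' @export
default_node_set <- function() {
  node_set(
    names = c(
      "nose", "left_ear", "right_ear", "neck",
      "left_forepaw", "right_forepaw", "left_hindpaw", "right_hindpaw",
      "base", "active_lever", "inactive_lever", "cue_light", "catheter"
    ),
    anchor = "catheter"
  )
}

#' Reduced six-node skeleton
#'
#' The trunk-only subset (nose, ears, neck, tail base, catheter) sufficient
#' for every locomotion and zone metric in the package.
#'
#' @return A `node_set`.
#' @export
reduced_node_set <- function() {
  node_set(c("nose", "left_ear", "right_ear", "neck", "base", "catheter"),
           anchor = "catheter")
}

#' Construct a node set
#'
#' @param names Character vector of unique node labels.
#' @param anchor Label of the anchor node; must be one of `names`.
#' @return A `node_set` object (list with `names` and `anchor`).
#' @export
node_set <- function(names, anchor) {
  if (anyDuplicated(names)) {
    pl_stop("node labels must be unique", "prelever_schema_error")
  }
  if (length(anchor) != 1L || !anchor %in% names) {
    pl_stop("anchor must be one of the node labels", "prelever_schema_error")
  }
  structure(list(names = as.character(names), anchor = anchor),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("<node_set> ", length(x$names), " nodes, anchor = ", x$anchor, "\n",
      sep = "")
  invisible(x)
}

track_columns <- function(nodes) {
  as.vector(rbind(paste0(nodes$names, ".x"), paste0(nodes$names, ".y")))
}

#' Construct a pose track
#'
#' @param coords Data frame with a `frame` column (contiguous integers from
#'   0) and `<node>.x` / `<node>.y` pixel columns for every node in `nodes`.
#'   `NA` marks a missing detection.
#' @param frame_rate Frames per second of the recording.
#' @param nodes A [node_set()].
#' @param source_id Identity of the originating file (path or label).
#' @return A `pose_track` object.
#' @export
pose_track <- function(coords, frame_rate, nodes, source_id = "<memory>") {
  stopifnot(is.data.frame(coords), inherits(nodes, "node_set"))
  if (!is_scalar_number(frame_rate) || frame_rate <= 0) {
    pl_stop("frame_rate must be a positive number", "prelever_format_error")
  }
  needed <- c("frame", track_columns(nodes))
  missing_cols <- setdiff(needed, names(coords))
  if (length(missing_cols)) {
    pl_stop(paste0("track is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            "prelever_schema_error")
  }
  fr <- coords$frame
  n <- length(fr)
  if (n > 0L && !identical(as.integer(fr), seq_len(n) - 1L)) {
    pl_stop("frame index must be contiguous integers starting at 0",
            "prelever_format_error")
  }
  coords$frame <- as.integer(fr)
  structure(
    list(coords = coords[needed], frame_rate = frame_rate, nodes = nodes,
         source_id = source_id),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> ", n_frames(x), " frames @ ", x$frame_rate, " fps, ",
      length(x$nodes$names), " nodes [", x$source_id, "]\n", sep = "")
  invisible(x)
}

#' Number of frames in a track
#' @param track A `pose_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) nrow(track$coords)

#' Extract one node's (x, y) series
#'
#' @param track A `pose_track`.
#' @param node Node label.
#' @return Numeric matrix with columns `x`, `y`, one row per frame.
#' @export
node_positions <- function(track, node) {
  if (!node %in% track$nodes$names) {
    pl_stop(paste0("unknown node: ", node), "prelever_schema_error")
  }
  m <- cbind(x = track$coords[[paste0(node, ".x")]],
             y = track$coords[[paste0(node, ".y")]])
  m
}

#' Read a delimited pose-track table
#'
#' Expects one row per frame with columns `frame`, then `<node>.x`,
#' `<node>.y` for every node in `nodes`. Empty fields are missing
#' detections; zeros are coordinates.
#'
#' @param path Path to the delimited text file (comma-separated).
#' @param nodes A [node_set()] naming the expected columns.
#' @param frame_rate Frames per second (default 10, the recording rate).
#' @return A [pose_track()].
#' @export
read_track_csv <- function(path, nodes, frame_rate = 10) {
  if (!file.exists(path)) {
    pl_stop(paste0("cannot read track file: ", path), "prelever_read_error")
  }
  df <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) {
      pl_stop(paste0("failed to parse ", path, ": ", conditionMessage(e)),
              "prelever_read_error")
    }
  )
  missing_cols <- setdiff(c("frame", track_columns(nodes)), names(df))
  if (length(missing_cols)) {
    pl_stop(paste0(path, " lacks columns: ",
                   paste(missing_cols, collapse = ", ")),
            "prelever_schema_error")
  }
  fr <- df$frame
  if (length(fr) && !identical(as.integer(fr), seq_along(fr) - 1L)) {
    pl_stop(paste0(path, ": frame index has gaps or is non-monotone"),
            "prelever_format_error")
  }
  pose_track(df, frame_rate = frame_rate, nodes = nodes, source_id = path)
}

#' Write a pose track in the delimited dialect
#'
#' Coordinates are serialized with 17 significant digits so a write/read
#' round trip reproduces every finite double bit-exactly; missing values
#' become empty fields.
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  df <- track$coords
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[!is.finite(v)] <- ""
    out
  }
  cols <- c(list(frame = format(as.integer(df$frame), scientific = FALSE)),
            lapply(df[-1L], fmt))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(cols), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Fill missing detections by linear interpolation
#'
#' Each node's x and y series is interpolated linearly over the frame index;
#' missing runs at either end are filled by holding the nearest observed
#' value. A node with no observation at all cannot be repaired.
#'
#' @param track A [pose_track()].
#' @return A `pose_track` with no missing coordinates.
#' @export
interpolate_missing <- function(track) {
  df <- track$coords
  for (col in names(df)[-1L]) {
    v <- df[[col]]
    obs <- which(is.finite(v))
    if (length(obs) == length(v)) next
    if (length(obs) == 0L) {
      pl_stop(paste0("node ", sub("\\.[xy]$", "", col),
                     " has no observed coordinates; track is irreparable"),
              "prelever_irreparable_track_error")
    }
    if (length(obs) == 1L) {
      df[[col]] <- rep(v[obs], length(v))
    } else {
      df[[col]] <- approx(obs, v[obs], xout = seq_along(v), rule = 2)$y
    }
  }
  track$coords <- df
  track
}

#' Pixel-to-centimeter calibration
#'
#' @param known_cm Known physical lengths in centimeters.
#' @param measured_px Corresponding measured pixel lengths.
#' @param orientation Optional character vector (`"length"`/`"width"`) per
#'   measurement; recorded but not used in the computation.
#' @return A `calibration_spec` carrying the measurements and the derived
#'   `cm_per_px` scalar.
#' @export
calibration_spec <- function(known_cm, measured_px,
                             orientation = rep(NA_character_,
                                               length(known_cm))) {
  if (length(known_cm) != length(measured_px)) {
    pl_stop("known_cm and measured_px lengths differ",
            "prelever_domain_error")
  }
  structure(
    list(measurements = data.frame(known_cm = known_cm,
                                   measured_px = measured_px,
                                   orientation = orientation),
         cm_per_px = compute_cm_per_px(known_cm, measured_px)),
    class = "calibration_spec"
  )
}

#' Compute the cm-per-pixel conversion factor
#'
#' The factor is the mean of the per-measurement ratios known_cm /
#' measured_px (not the ratio of summed quantities), which tolerates mixing
#' chamber length and width measurements of different physical sizes —
#' relevant under fisheye barrel distortion, where the ratio varies across
#' the image and averaging several measurements is the standard correction.
#'
#' @param known_cm,measured_px Positive numeric vectors of equal length.
#' @return Scalar cm/pixel.
#' @export
compute_cm_per_px <- function(known_cm, measured_px) {
  if (length(known_cm) < 1L) {
    pl_stop("at least one calibration measurement required",
            "prelever_domain_error")
  }
  if (any(!is.finite(known_cm)) || any(!is.finite(measured_px)) ||
      any(known_cm <= 0) || any(measured_px <= 0)) {
    pl_stop("calibration measurements must be positive and finite",
            "prelever_domain_error")
  }
  mean(known_cm / measured_px)
}

#' Split a track at lever extension
#'
#' Returns the `segment_len` frames ending at the lever-extension frame
#' (the pre-lever segment, no drug available) and the `segment_len` frames
#' starting there (post-lever), both re-indexed from frame 0. A side with
#' fewer frames than requested is truncated with a classed warning
#' (`prelever_truncation_warning`) carrying the realized lengths; callers
#' log it rather than failing.
#'
#' @param track A [pose_track()].
#' @param lever_extension_frame Frame index at which levers extended.
#' @param segment_len Frames per side; default 12.5 minutes at the track's
#'   frame rate, the aligned length the processing pipeline standardizes to.
#' @return List with `pre` and `post` pose tracks.
#' @export
align_to_lever_extension <- function(track, lever_extension_frame,
                                     segment_len = round(12.5 * 60 *
                                                           track$frame_rate)) {
  f <- lever_extension_frame
  if (is.null(f) || length(f) != 1L || is.na(f)) {
    pl_stop(paste0("no lever-extension frame: use the whole-session path ",
                   "for noncontingent recordings"),
            "prelever_contract_error")
  }
  f <- as.integer(f)
  n <- n_frames(track)
  if (f < 0L || f > n) {
    pl_stop("lever_extension_frame outside the recording",
            "prelever_contract_error")
  }
  pre_len <- min(segment_len, f)
  post_len <- min(segment_len, n - f)
  if (pre_len < segment_len || post_len < segment_len) {
    pl_warn(sprintf(
      "segment truncated: pre %d, post %d of %d requested frames",
      pre_len, post_len, as.integer(segment_len)),
      "prelever_truncation_warning",
      pre_len = pre_len, post_len = post_len)
  }
  take <- function(idx) {
    df <- track$coords[idx, , drop = FALSE]
    df$frame <- seq_len(nrow(df)) - 1L
    rownames(df) <- NULL
    pose_track(df, track$frame_rate, track$nodes,
               source_id = track$source_id)
  }
  # frame index is 0-based; row i holds frame i-1
  list(pre = take(seq_len(pre_len) + (f - pre_len)),
       post = take(f + seq_len(post_len)))
}

#' Read a session manifest
#'
#' One row per recording: `subject_id`, `session_label`, `session_type`,
#' `date`, `start_time`, `duration_h`, `lever_extension_frame` (empty for
#' noncontingent phases), `track_path`.
#'
#' @param path Delimited-text manifest path.
#' @return Data frame with a `start` POSIXct column appended.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    pl_stop(paste0("manifest not found: ", path), "prelever_read_error")
  }
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(lever_extension_frame = "integer"))
  needed <- c("subject_id", "session_label", "session_type", "date",
              "start_time", "duration_h", "lever_extension_frame",
              "track_path")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    pl_stop(paste0("manifest lacks columns: ",
                   paste(missing_cols, collapse = ", ")),
            "prelever_schema_error")
  }
  df$start <- as.POSIXct(paste(df$date, df$start_time), tz = "UTC")
  df
}

#' Read a run configuration file
#'
#' YAML document with calibration measurements, frame rate, segment length,
#' zone half-extents, smoothing window, and chamber bounds. Absent keys take
#' package defaults.
#'
#' @param path YAML file path (optional; `NULL` yields defaults).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    frame_rate = 10,
    segment_min = 12.5,
    smooth_window = 10,
    zone_half_x = 30,
    zone_half_y = 18,
    winsor_q = 0.95,
    epm_eps_m = 0.01,
    smooth_entrances = FALSE,
    scoring_sessions = c("ShortAccess07", "ShortAccess08", "ShortAccess09"),
    chamber = c(xmin = 0, xmax = 270, ymin = 0, ymax = 162),
    calibration = list(known_cm = c(30, 30, 18, 18, 18),
                       measured_px = c(270, 270, 162, 162, 162))
  )
  out <- utils::modifyList(defaults, cfg)
  out$cm_per_px <- out$cm_per_px %||%
    compute_cm_per_px(out$calibration$known_cm, out$calibration$measured_px)
  out$chamber <- unlist(out$chamber)
  out
}
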