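# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# Minimal hand-built track, by default on the reduced six-node skeleton.
# `paths` is a named list of n x 2 matrices (one per node); nodes not
# listed sit at a fixed point.
make_track <- function(paths, n = NULL, frame_rate = 10,
                       nodes = reduced_node_set()) {
  n <- n %||% nrow(paths[[1]])
  coords <- data.frame(frame = seq_len(n) - 1L)
  for (nm in nodes$names) {
    m <- if (nm %in% names(paths)) paths[[nm]] else
      matrix(rep(c(5, 5), each = n), ncol = 2)
    coords[[paste0(nm, ".x")]] <- m[, 1]
    coords[[paste0(nm, ".y")]] <- m[, 2]
  }
  pose_track(coords, frame_rate = frame_rate, nodes = nodes)
}

# Reduced skeleton plus the lever nodes, for zone tests.
lever_node_set <- function() {
  node_set(c(reduced_node_set()$names, "active_lever", "inactive_lever"),
           anchor = "catheter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pre-lever style metrics for one simulated session.
sim_session_metrics <- function(lambda, gain = 1, seed = 1, nf = 2500,
                                dropout_p = 0) {
  p <- trajectory_params(lever_attraction = lambda, locomotor_gain = gain,
                         seed = seed, dropout_p = dropout_p)
  tr <- simulate_trajectory(p, n_frames = nf)
  tr <- interpolate_missing(tr)
  zone <- make_lever_zone(tr, "active_lever")
  loco <- path_length(smooth_positions(tr, "catheter", 10), 0.111)
  n_ent <- count_zone_entrances(node_positions(tr, "nose"), zone)
  c(loco = loco, epm = entrances_per_meter(n_ent, loco), entrances = n_ent)
}

# Literal frame-by-frame state machine: the independent oracle for
# entrance counting.
oracle_entrances <- function(xy, box) {
  inside_prev <- NA
  count <- 0L
  for (i in seq_len(nrow(xy))) {
    inside <- abs(xy[i, 1] - box$center[1]) <= box$half_x &&
      abs(xy[i, 2] - box$center[2]) <= box$half_y
    if (!is.na(inside_prev) && inside && !inside_prev) count <- count + 1L
    inside_prev <- inside
  }
  count
}

# A reduced timeline carrying the sessions the scoring pipeline needs.
mini_timeline <- function() {
  tl <- default_timeline()
  keep <- tl$session_label %in% c(
    "ShortAccess07", "ShortAccess08", "ShortAccess09",
    "Baseline01", "Saline01", "Drug01",
    "Baseline03", "Saline03", "Drug03")
  tl[keep, ]
}
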