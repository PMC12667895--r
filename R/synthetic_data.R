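# Synthetic pose tracks and operant event streams with the statistical
# structure the analysis assumes: a correlated-random-walk rat whose
# lever-zone attraction and locomotor gain are planted, recoverable
# parameters, plus Poisson press streams pushed through the reinforcement
# schedule. Everything is reproducible from seeds.

#' Default chamber rectangle, pixels
#'
#' A 30 cm x 18 cm floor imaged at ~0.111 cm/px: 270 x 162 px, origin
#' top-left (video convention).
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
default_chamber <- function() c(xmin = 0, xmax = 270, ymin = 0, ymax = 162)

#' Default static chamber-node positions
#' @return Named list of (x, y) pixel positions for `active_lever`,
#'   `inactive_lever`, `cue_light`.
#' @export
default_zones <- function() {
  list(active_lever = c(40, 81), inactive_lever = c(230, 81),
       cue_light = c(40, 20))
}

#' Trajectory-generator parameters
#'
#' @param persistence Heading autocorrelation rho in \[0, 1): how strongly
#'   the current heading carries over between frames.
#' @param step_scale Mean step length in px/frame (exponential steps).
#' @param lever_attraction Lever-seeking propensity lambda in \[0, 1\] —
#'   the planted incentive-salience knob; a seeking bout toward the
#'   active-lever zone starts with per-frame probability `lambda / 50`.
#' @param locomotor_gain Multiplier g > 0 on the step scale — the planted
#'   drug-state / sensitization knob.
#' @param dropout_p Per-frame, per-node missing-detection probability in
#'   \[0, 1).
#' @param seed Integer RNG seed.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(persistence = 0.7, step_scale = 3,
                              lever_attraction = 0.1, locomotor_gain = 1,
                              dropout_p = 0.02, seed = 1L) {
  if (persistence < 0 || persistence >= 1) {
    pl_stop("persistence must lie in [0, 1)", "prelever_parameter_error")
  }
  if (lever_attraction < 0 || lever_attraction > 1) {
    pl_stop("lever_attraction must lie in [0, 1]",
            "prelever_parameter_error")
  }
  if (locomotor_gain <= 0 || step_scale < 0) {
    pl_stop("locomotor_gain must be > 0 and step_scale >= 0",
            "prelever_parameter_error")
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    pl_stop("dropout_p must lie in [0, 1)", "prelever_parameter_error")
  }
  structure(list(persistence = persistence, step_scale = step_scale,
                 lever_attraction = lever_attraction,
                 locomotor_gain = locomotor_gain, dropout_p = dropout_p,
                 seed = as.integer(seed)),
            class = "trajectory_params")
}

# Rigid body offsets (px) from the catheter anchor, expressed in the
# animal's heading frame (forward, leftward).
body_offsets <- list(
  nose = c(18, 0), left_ear = c(14, 4), right_ear = c(14, -4),
  neck = c(9, 0),
  left_forepaw = c(10, 5), right_forepaw = c(10, -5),
  left_hindpaw = c(-2, 5), right_hindpaw = c(-2, -5),
  base = c(-10, 0), catheter = c(0, 0)
)

#' Simulate a pose track
#'
#' The catheter anchor performs a correlated random walk with exponential
#' step lengths and reflecting chamber walls, interleaved with seeking
#' bouts: with per-frame probability `lever_attraction / 50` the walker
#' starts drifting toward the active-lever zone center and stops on
#' arrival within `attract_radius`. During a bout steps are drawn
#' `seek_speed` times longer — goal-directed approach runs faster than
#' exploratory ambling — so seeking propensity raises both lever-zone
#' entrances and locomotion, the coupled expression of incentive salience
#' the composite score assumes. Body nodes ride as rigid offsets
#' in the heading frame plus small Gaussian jitter; lever and cue nodes
#' are static with jitter. Dropout removes node-frames i.i.d. Fully
#' reproducible from the seed.
#'
#' @param p A [trajectory_params()].
#' @param n_frames Frames to simulate (default 18000 = 30 min at 10 fps).
#' @param chamber Chamber rectangle, `c(xmin, xmax, ymin, ymax)`.
#' @param zones Named list of static node positions (see
#'   [default_zones()]); the active lever is the attraction target.
#' @param frame_rate Frames per second recorded on the track.
#' @param jitter_sd Keypoint jitter standard deviation, px.
#' @param attract_radius Arrival distance (px) ending a seeking bout;
#'   defaults to the lever-zone x half-extent.
#' @param seek_weight Drift weight during a seeking bout.
#' @param seek_speed Step-length multiplier during a seeking bout.
#' @return A [pose_track()] with the full thirteen-node set.
#' @export
simulate_trajectory <- function(p, n_frames = 18000,
                                chamber = default_chamber(),
                                zones = default_zones(), frame_rate = 10,
                                jitter_sd = 0.5, attract_radius = 30,
                                seek_weight = 0.8, seek_speed = 1.5) {
  stopifnot(inherits(p, "trajectory_params"), n_frames >= 1)
  ch <- unname(chamber[c("xmin", "xmax", "ymin", "ymax")])
  for (z in zones) {
    if (z[1] < ch[1] || z[1] > ch[2] || z[2] < ch[3] || z[2] > ch[4]) {
      pl_stop("zone center outside the chamber", "prelever_parameter_error")
    }
  }
  set.seed(p$seed)
  start <- c(mean(ch[1:2]), mean(ch[3:4]))
  core <- crw_core(as.integer(n_frames), p$persistence,
                   p$step_scale * p$locomotor_gain,
                   ch, zones$active_lever, start, attract_radius,
                   p$lever_attraction / 50, seek_weight, seek_speed)
  pos <- core$pos
  hd <- core$heading
  perp <- cbind(-hd[, 2], hd[, 1])
  clamp <- function(m) {
    cbind(pmin(pmax(m[, 1], ch[1]), ch[2]),
          pmin(pmax(m[, 2], ch[3]), ch[4]))
  }
  nodes <- default_node_set()
  coords <- data.frame(frame = seq_len(n_frames) - 1L)
  for (nm in nodes$names) {
    if (nm %in% names(zones)) {
      m <- cbind(rep(zones[[nm]][1], n_frames),
                 rep(zones[[nm]][2], n_frames))
    } else {
      off <- body_offsets[[nm]]
      m <- pos + off[1] * hd + off[2] * perp
    }
    m <- m + matrix(rnorm(2L * n_frames, sd = jitter_sd), ncol = 2)
    m <- clamp(m)
    if (p$dropout_p > 0) {
      drop <- runif(n_frames) < p$dropout_p
      m[drop, ] <- NA_real_
    }
    coords[[paste0(nm, ".x")]] <- round(m[, 1], 3)
    coords[[paste0(nm, ".y")]] <- round(m[, 2], 3)
  }
  pose_track(coords, frame_rate = frame_rate, nodes = nodes,
             source_id = sprintf("sim(seed=%d)", p$seed))
}

#' Simulate a self-administration event stream
#'
#' Lever presses arrive as a Poisson stream at `press_rate`; the schedule
#' (fixed-ratio 1 or progressive ratio) converts presses into infusions.
#' Presses during the pump + timeout lockout have no programmed effect.
#' In Shock sessions each infusion is paired with a footshock with
#' probability `pair_prob`.
#'
#' @param press_rate Presses per minute (>= 0).
#' @param duration_h Session length in hours.
#' @param schedule `"FR1"` or `"PR"`.
#' @param drug A [drug_config()] (pump and timeout durations).
#' @param shock A [shock_config()].
#' @param shock_session Logical; pair infusions with shock?
#' @param seed Integer RNG seed.
#' @return Data frame of infusion events: `time_s`, `ratio_completed`,
#'   `shocked`.
#' @export
simulate_sa_session <- function(press_rate, duration_h = 2,
                                schedule = c("FR1", "PR"),
                                drug = drug_config(),
                                shock = shock_config(),
                                shock_session = FALSE, seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(press_rate >= 0, duration_h > 0)
  set.seed(seed)
  len_s <- duration_h * 3600
  n_press <- rpois(1, press_rate * duration_h * 60)
  if (n_press == 0L) {
    return(data.frame(time_s = numeric(), ratio_completed = integer(),
                      shocked = logical()))
  }
  presses <- sort(runif(n_press, 0, len_s))
  lockout <- drug$sa_pump_s + drug$timeout_s
  times <- numeric(0)
  ratios <- integer(0)
  lock_until <- -Inf
  count <- 0L
  k <- 1L
  req <- if (schedule == "FR1") 1L else pr_requirement(1L)
  for (t in presses) {
    if (t < lock_until) next
    count <- count + 1L
    if (count >= req) {
      times <- c(times, t)
      ratios <- c(ratios, req)
      lock_until <- t + lockout
      count <- 0L
      k <- k + 1L
      req <- if (schedule == "FR1") 1L else pr_requirement(k)
    }
  }
  shocked <- if (shock_session && length(times)) {
    runif(length(times)) < shock$pair_prob
  } else {
    rep(FALSE, length(times))
  }
  data.frame(time_s = times, ratio_completed = ratios, shocked = shocked)
}

#' Simulate a noncontingent session (Baseline / Saline / Drug phases)
#'
#' Three 30-minute tracks from three parameter sets; the Drug phase's
#' locomotor gain is multiplied by `drug_gain`, emulating the psychomotor
#' response to the noncontingent infusion.
#'
#' @param params List of three [trajectory_params()] named `baseline`,
#'   `saline`, `drug` (seeds should differ between phases).
#' @param drug_gain Multiplier applied to the drug phase's locomotor gain.
#' @param n_frames Frames per phase.
#' @param ... Passed to [simulate_trajectory()].
#' @return Named list of three [pose_track()]s.
#' @export
simulate_noncontingent_session <- function(params, drug_gain = 1.5,
                                           n_frames = 18000, ...) {
  stopifnot(all(c("baseline", "saline", "drug") %in% names(params)))
  pd <- params$drug
  pd$locomotor_gain <- pd$locomotor_gain * drug_gain
  list(baseline = simulate_trajectory(params$baseline, n_frames, ...),
       saline = simulate_trajectory(params$saline, n_frames, ...),
       drug = simulate_trajectory(pd, n_frames, ...))
}

#' Derive a per-file seed from the master seed and file identity
#'
#' Stable 31-bit polynomial hash of `(master_seed, subject_id,
#' session_label)`, so any single fixture file can be regenerated in
#' isolation.
#'
#' @param master_seed Integer master seed.
#' @param subject_id,session_label File identity.
#' @return Positive integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, subject_id, session_label) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(paste(subject_id, session_label, sep = "/"))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(1, h))
}

#' Fixture-set specification
#'
#' @param n_subjects Cohort size (default 37).
#' @param timeline Session templates from [default_timeline()].
#' @param n_frames Frames per self-administration track (the study records
#'   30 min at 10 fps = 18000; reduce for fast fixtures).
#' @param nc_frames Frames per noncontingent phase track (default
#'   `n_frames`).
#' @param base_params Baseline [trajectory_params()].
#' @param param_fn Optional `function(subject_id, session_label,
#'   session_type, base)` returning the [trajectory_params()] for one file
#'   (seed is re-derived afterwards); use it to plant per-subject
#'   attraction or gain schedules.
#' @param press_rates Named presses/min per session type.
#' @param exclude Character vector of `"subject_id/session_label"` keys to
#'   flag excluded in the manifest (files are still written, mirroring
#'   whole-file failures excluded downstream).
#' @param master_seed Integer master seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_subjects = 37, timeline = default_timeline(),
                         n_frames = 18000, nc_frames = n_frames,
                         base_params = trajectory_params(),
                         param_fn = NULL,
                         press_rates = c(ShortAccess = 2, LongAccess = 2,
                                         Preshock = 2, Shock = 2,
                                         ProgressiveRatio = 4),
                         exclude = character(), master_seed = 1L) {
  stopifnot(n_subjects >= 1)
  # reduced timelines (subsets of sessions) are allowed for fast fixtures;
  # default_timeline() itself is validated at construction
  structure(list(n_subjects = n_subjects, timeline = timeline,
                 n_frames = n_frames, nc_frames = nc_frames,
                 base_params = base_params, param_fn = param_fn,
                 press_rates = press_rates, exclude = exclude,
                 master_seed = as.integer(master_seed)),
            class = "fixture_spec")
}

#' Build a fixture tree: track files, event log, and manifest
#'
#' Writes one track file per subject per self-administration session and
#' per noncontingent phase, an event log of simulated infusions for the
#' self-administration sessions, and a manifest consumable by
#' [read_manifest()]. Deterministic given the master seed: per-file seeds
#' come from [derive_seed()]. At the full study scale (37 subjects, the
#' canonical timeline) this yields 1110 self-administration and 333
#' noncontingent track files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output root (created if needed).
#' @return The manifest data frame, invisibly, with attributes
#'   `n_sa_files`, `n_nc_files`, `events_path`, `manifest_path`.
#' @export
build_fixture_set <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  track_dir <- file.path(dir, "tracks")
  ok <- dir.create(track_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(track_dir)) {
    pl_stop(paste0("cannot create output root: ", dir), "prelever_io_error")
  }
  subjects <- sprintf("R%03d", seq_len(spec$n_subjects))
  tl <- spec$timeline
  is_sa <- tl$session_type %in% sa_session_types
  rows <- vector("list", spec$n_subjects * nrow(tl))
  events <- vector("list", 0)
  n_sa <- 0L
  n_nc <- 0L
  ri <- 0L
  for (s in subjects) {
    for (j in seq_len(nrow(tl))) {
      lab <- tl$session_label[j]
      type <- tl$session_type[j]
      nf <- if (is_sa[j]) spec$n_frames else spec$nc_frames
      p <- spec$base_params
      if (!is.null(spec$param_fn)) p <- spec$param_fn(s, lab, type, p)
      p$seed <- derive_seed(spec$master_seed, s, lab)
      track <- simulate_trajectory(p, n_frames = nf)
      rel <- file.path("tracks", paste0(s, "_", lab, ".csv"))
      write_track_csv(track, file.path(dir, rel))
      ext <- if (is_sa[j]) as.integer(nf %/% 2L) else NA_integer_
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        subject_id = s, session_label = lab, session_type = type,
        date = tl$date[j], start_time = tl$start_time[j],
        duration_h = tl$duration_h[j], lever_extension_frame = ext,
        track_path = rel,
        excluded = paste0(s, "/", lab) %in% spec$exclude,
        stringsAsFactors = FALSE
      )
      if (is_sa[j]) {
        n_sa <- n_sa + 1L
        ev <- simulate_sa_session(
          press_rate = unname(spec$press_rates[type]),
          duration_h = tl$duration_h[j],
          schedule = if (type == "ProgressiveRatio") "PR" else "FR1",
          shock_session = type == "Shock",
          seed = derive_seed(spec$master_seed, s, paste0(lab, "#events"))
        )
        if (nrow(ev)) {
          ev <- cbind(session_label = lab, subject_id = s, ev,
                      stringsAsFactors = FALSE)
          events[[length(events) + 1L]] <- ev
        }
      } else {
        n_nc <- n_nc + 1L
      }
    }
  }
  manifest <- do.call(rbind, rows[seq_len(ri)])
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, na = "")
  events_df <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(session_label = character(), subject_id = character(),
               time_s = numeric(), ratio_completed = integer(),
               shocked = logical())
  }
  events_path <- file.path(dir, "events.csv")
  write.csv(events_df, events_path, row.names = FALSE)
  attr(manifest, "n_sa_files") <- n_sa
  attr(manifest, "n_nc_files") <- n_nc
  attr(manifest, "events_path") <- events_path
  attr(manifest, "manifest_path") <- manifest_path
  invisible(manifest)
}
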