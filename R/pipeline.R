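# End-to-end orchestration: manifest in, tidy metrics / scores /
# correlations / heatmaps out. Stage outputs are pure functions of
# (inputs, config); every run can emit a self-describing log.

segment_metrics <- function(track, cfg, segment) {
  loco_xy <- smooth_positions(track, track$nodes$anchor,
                              cfg$smooth_window)
  nose_sm <- smooth_positions(track, "nose", cfg$smooth_window)
  nose_raw <- node_positions(track, "nose")
  nose_for_zones <- if (isTRUE(cfg$smooth_entrances)) nose_sm else nose_raw
  act <- make_lever_zone(track, "active_lever",
                         cfg$zone_half_x, cfg$zone_half_y)
  inact <- make_lever_zone(track, "inactive_lever",
                           cfg$zone_half_x, cfg$zone_half_y)
  loco_m <- path_length(loco_xy, cfg$cm_per_px)
  n_act <- count_zone_entrances(nose_for_zones, act)
  n_inact <- count_zone_entrances(nose_for_zones, inact)
  data.frame(
    segment = segment,
    n_frames = n_frames(track),
    loco_m = loco_m,
    nose_m = path_length(nose_sm, cfg$cm_per_px),
    active_entrances = n_act,
    inactive_entrances = n_inact,
    epm = entrances_per_meter(n_act, loco_m, cfg$epm_eps_m),
    inactive_epm = entrances_per_meter(n_inact, loco_m, cfg$epm_eps_m),
    stringsAsFactors = FALSE
  )
}

#' Compute the per-session behavioral metrics table
#'
#' For every non-excluded manifest row: read the track, interpolate missing
#' detections, build the lever zones, and compute locomotion, nose motion,
#' entrances, and entrances per meter. Lever sessions produce a `pre` and a
#' `post` row (split at lever extension); noncontingent phases one `whole`
#' row. Unreadable or irreparable files are logged and skipped, never
#' fatal.
#'
#' @param manifest Manifest data frame from [read_manifest()] (or the
#'   return of [build_fixture_set()]).
#' @param cfg Run configuration from [read_run_config()].
#' @param base_dir Directory that `track_path` entries are relative to.
#' @return Tidy data frame, one row per subject x session x segment, with
#'   a `log` attribute recording skipped files and truncation notices.
#' @export
run_metrics <- function(manifest, cfg = read_run_config(),
                        base_dir = ".") {
  if (is.null(manifest) || nrow(manifest) == 0L) {
    pl_stop("empty manifest", "prelever_contract_error")
  }
  if (is.null(manifest$excluded)) manifest$excluded <- FALSE
  nodes <- default_node_set()
  rows <- list()
  log <- list(skipped = character(), truncated = character(),
              excluded = character())
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    tag <- paste0(m$subject_id, "/", m$session_label)
    if (isTRUE(m$excluded)) {
      log$excluded <- c(log$excluded, tag)
      next
    }
    res <- tryCatch({
      track <- read_track_csv(file.path(base_dir, m$track_path), nodes,
                              cfg$frame_rate)
      track <- interpolate_missing(track)
      if (!is.na(m$lever_extension_frame)) {
        segs <- withCallingHandlers(
          align_to_lever_extension(
            track, m$lever_extension_frame,
            segment_len = round(cfg$segment_min * 60 * cfg$frame_rate)),
          prelever_truncation_warning = function(w) {
            log$truncated <<- c(log$truncated,
                                paste0(tag, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        rbind(segment_metrics(segs$pre, cfg, "pre"),
              segment_metrics(segs$post, cfg, "post"))
      } else {
        segment_metrics(track, cfg, "whole")
      }
    }, prelever_error = function(e) {
      log$skipped <<- c(log$skipped,
                        paste0(tag, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      res <- cbind(subject_id = m$subject_id,
                   session_label = m$session_label,
                   session_type = m$session_type, res,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    pl_stop("no manifest row could be processed", "prelever_contract_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Subject-level scores from the metrics table
#'
#' Computes the pre-lever activity composite with its High/Low split over
#' the scoring window (Short Access 07-09 by default), the
#' sensitization/tolerance expression labels from noncontingent Drug-phase
#' locomotion (percent change from the first Drug session), and the
#' abstinence code preceding every session.
#'
#' @param metrics Metrics table from [run_metrics()].
#' @param manifest Session manifest (needs `start` times for abstinence;
#'   see [read_manifest()]).
#' @param cfg Run configuration.
#' @return List with `scores` (composite + group + expression label per
#'   subject), `abstinence` (per subject x session), and `expression`.
#' @export
run_scoring <- function(metrics, manifest = NULL,
                        cfg = read_run_config()) {
  pre <- metrics[metrics$segment == "pre" &
                   metrics$session_label %in% cfg$scoring_sessions, ]
  if (nrow(pre) == 0L) {
    pl_stop("metrics table lacks the scoring-window pre-lever sessions",
            "prelever_contract_error")
  }
  scores <- composite_prelever_zscore(
    data.frame(subject_id = pre$subject_id,
               session_label = pre$session_label,
               loco_m = pre$loco_m, epm = pre$epm,
               stringsAsFactors = FALSE),
    sessions = cfg$scoring_sessions)

  drug <- metrics[metrics$session_type == "NoncontingentDrug", ]
  expression <- NULL
  if (nrow(drug)) {
    label_of <- function(lab) drug[drug$session_label == lab, ]
    d1 <- label_of("Drug01")
    d3 <- label_of("Drug03")
    subj <- sort(unique(drug$subject_id))
    l1 <- d1$loco_m[match(subj, d1$subject_id)]
    l3 <- d3$loco_m[match(subj, d3$subject_id)]
    expression <- classify_expression(data.frame(
      subject_id = subj,
      drug01 = ifelse(is.finite(l1), 0, NA_real_),
      drug03 = percent_diff_baseline(l3, l1),
      stringsAsFactors = FALSE))
    scores$expression <- expression$label[match(scores$subject_id,
                                                expression$subject_id)]
    scores$delta <- expression$delta[match(scores$subject_id,
                                           expression$subject_id)]
  }

  abstinence <- NULL
  if (!is.null(manifest)) {
    manifest <- ensure_session_start(manifest)
    abstinence <- do.call(rbind, lapply(
      split(manifest, manifest$subject_id),
      function(m) {
        cbind(subject_id = m$subject_id[1], abstinence_codes(m),
              stringsAsFactors = FALSE)
      }))
    rownames(abstinence) <- NULL
  }
  list(scores = scores, expression = expression, abstinence = abstinence)
}

count_early_infusions <- function(events, window_s = 900) {
  ev <- events[events$time_s <= window_s, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(subject_id = character(), session_label = character(),
                      infusions_15min = integer()))
  }
  agg <- stats::aggregate(time_s ~ subject_id + session_label, data = ev,
                          FUN = length)
  names(agg)[3] <- "infusions_15min"
  agg
}

#' Correlation tables, occupancy heatmaps, and a run summary
#'
#' Correlates pre-lever activity (locomotion and entrances per meter)
#' against infusions earned in the first 15 minutes, per session type, with
#' Benjamini-Yekutieli adjustment across the table; overlays nose occupancy
#' grids per noncontingent block; and assembles a short text summary.
#'
#' @param metrics Metrics table from [run_metrics()].
#' @param scores Output of [run_scoring()].
#' @param events Infusion event log (columns `subject_id`,
#'   `session_label`, `time_s`, ...).
#' @param manifest Manifest (used to locate noncontingent tracks for the
#'   heatmaps; heatmaps are skipped when `NULL`).
#' @param cfg Run configuration.
#' @param base_dir Directory track paths are relative to.
#' @param bins Heatmap bin counts, `c(nx, ny)`.
#' @return List with `correlations`, `heatmaps` (named list of
#'   `occupancy_grid`s), and `summary` (character lines).
#' @export
run_report <- function(metrics, scores, events, manifest = NULL,
                       cfg = read_run_config(), base_dir = ".",
                       bins = c(27L, 16L)) {
  pre <- metrics[metrics$segment == "pre", ]
  early <- count_early_infusions(events)
  merged <- merge(pre, early, by = c("subject_id", "session_label"))
  rows <- list()
  for (type in unique(merged$session_type)) {
    d <- merged[merged$session_type == type, ]
    for (var in c("loco_m", "epm")) {
      ok <- is.finite(d[[var]]) & is.finite(d$infusions_15min)
      if (sum(ok) < 3L || sd(d[[var]][ok]) == 0 ||
          sd(d$infusions_15min[ok]) == 0) next
      ct <- choose_and_correlate(d[[var]][ok], d$infusions_15min[ok],
                                 alpha_norm = 0.05)
      ct <- cbind(session_type = type, variable = var, ct,
                  stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- ct
    }
  }
  correlations <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(correlations)) {
    correlations$p_adj <- by_adjust(correlations$p_raw)
  }

  heatmaps <- list()
  if (!is.null(manifest)) {
    excl <- manifest$excluded
    if (is.null(excl)) excl <- rep(FALSE, nrow(manifest))
    excl[is.na(excl)] <- FALSE
    nc <- manifest[manifest$session_type %in% nc_session_types & !excl, ]
    if (nrow(nc)) {
      block <- sub("^[A-Za-z]+", "", nc$session_label)
      nodes <- default_node_set()
      for (b in sort(unique(block))) {
        grid <- NULL
        for (i in which(block == b)) {
          tr <- tryCatch(
            interpolate_missing(read_track_csv(
              file.path(base_dir, nc$track_path[i]), nodes,
              cfg$frame_rate)),
            prelever_error = function(e) NULL)
          if (is.null(tr)) next
          g <- occupancy_heatmap(node_positions(tr, "nose"), bins,
                                 cfg$chamber)
          grid <- if (is.null(grid)) g else grid + g
        }
        if (!is.null(grid)) heatmaps[[paste0("Noncontingent", b)]] <- grid
      }
    }
  }

  summary <- c(
    sprintf("sessions scored: %d rows, %d subjects", nrow(metrics),
            length(unique(metrics$subject_id))),
    sprintf("High/Low split: %d High, %d Low",
            sum(scores$scores$group == "High", na.rm = TRUE),
            sum(scores$scores$group == "Low", na.rm = TRUE)),
    if (!is.null(scores$expression)) {
      sprintf("expression: %d Sensitization, %d Tolerance, %d Unclassified",
              sum(scores$expression$label == "Sensitization"),
              sum(scores$expression$label == "Tolerance"),
              sum(scores$expression$label == "Unclassified"))
    },
    if (!is.null(correlations)) {
      sprintf("correlations: %d tests, %d with BY-adjusted p < 0.05",
              nrow(correlations), sum(correlations$p_adj < 0.05))
    }
  )
  list(correlations = correlations, heatmaps = heatmaps, summary = summary)
}

#' Write pipeline outputs and a reproducibility log
#'
#' Persists the metrics and scores tables, the correlation table, heatmap
#' grids with their geometry sidecars, and a YAML run log (config, seeds,
#' file accounting, exclusions) sufficient to reproduce the run.
#'
#' @param out_dir Output directory (created if needed).
#' @param metrics,scoring,report Stage outputs.
#' @param cfg Run configuration.
#' @param seed The run's master seed, recorded in the log.
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(out_dir, metrics, scoring = NULL,
                              report = NULL, cfg = read_run_config(),
                              seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE,
            na = "")
  if (!is.null(scoring)) {
    write.csv(scoring$scores, file.path(out_dir, "scores.csv"),
              row.names = FALSE, na = "")
    if (!is.null(scoring$abstinence)) {
      write.csv(scoring$abstinence, file.path(out_dir, "abstinence.csv"),
                row.names = FALSE)
    }
  }
  if (!is.null(report)) {
    if (!is.null(report$correlations)) {
      write.csv(report$correlations,
                file.path(out_dir, "correlations.csv"), row.names = FALSE)
    }
    for (nm in names(report$heatmaps)) {
      write_occupancy_grid(report$heatmaps[[nm]],
                           file.path(out_dir, paste0("heatmap_", nm,
                                                     ".csv")))
    }
    writeLines(report$summary, file.path(out_dir, "summary.txt"))
  }
  log <- attr(metrics, "log") %||% list()
  yaml::write_yaml(list(
    seed = seed,
    config = cfg[setdiff(names(cfg), "chamber")],
    chamber = as.list(cfg$chamber),
    n_metric_rows = nrow(metrics),
    skipped = log$skipped %||% character(),
    truncated_n = length(log$truncated %||% character()),
    excluded = log$excluded %||% character()
  ), file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
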