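# Subject-level derived scores: baseline normalizations, winsorization,
# the pre-lever activity composite with its High/Low median split,
# sensitization/tolerance labels, and categorical abstinence codes.

#' Percent difference from a baseline
#'
#' @param value Numeric vector of metric values.
#' @param baseline Scalar (or equal-length vector) baseline; a zero
#'   baseline yields `NA` (undefined), never `Inf`.
#' @return `(value - baseline) / baseline * 100`, vectorized.
#' @export
percent_diff_baseline <- function(value, baseline) {
  out <- (value - baseline) / baseline * 100
  out[baseline == 0] <- NA_real_
  out
}

#' Normalize values by a cohort baseline-session mean
#'
#' Expresses each subject's value as percent difference from the cohort
#' mean of a baseline session — the normalization used for lever-entrance
#' measures across noncontingent blocks, where raw individual variation is
#' high.
#'
#' @param values Numeric vector of per-subject metrics.
#' @param baseline_values Cohort values for the baseline session.
#' @return Numeric vector of percent differences.
#' @export
normalize_by_group_baseline_mean <- function(values, baseline_values) {
  b <- baseline_values[is.finite(baseline_values)]
  if (length(b) == 0L) {
    pl_stop("baseline cohort is empty", "prelever_contract_error")
  }
  percent_diff_baseline(values, mean(b))
}

#' Winsorize the upper tail
#'
#' Values above the empirical `q`-quantile are capped at that quantile;
#' everything at or below passes through. Uses the linear-interpolation
#' empirical quantile (R type 7), the conventional default.
#'
#' @param values Numeric vector with at least two finite values.
#' @param q Upper quantile in (0, 1); default 0.95.
#' @return Vector of the same length, `NA`s preserved in place.
#' @export
winsorize_upper <- function(values, q = 0.95) {
  if (!is_scalar_number(q) || q <= 0 || q >= 1) {
    pl_stop("q must lie in (0, 1)", "prelever_parameter_error")
  }
  if (sum(is.finite(values)) < 2L) {
    pl_stop("need at least two finite values to winsorize",
            "prelever_contract_error")
  }
  cap <- quantile(values, q, na.rm = TRUE, names = FALSE, type = 7)
  pmin(values, cap)
}

#' Composite pre-lever activity score and High/Low split
#'
#' For each subject, pre-lever locomotion and active-lever entrances per
#' meter are averaged over the three target sessions (over whichever of the
#' three are available when some are missing; the realized session count is
#' returned). Each per-subject mean is standardized across the cohort, the
#' two z-scores are averaged into the composite, and subjects at or above
#' the cohort median composite are labeled High, the rest Low. Higher
#' scores mean more pre-session activity — the incentive-salience readout.
#'
#' @param metrics Data frame with columns `subject_id`, `session_label`,
#'   `loco_m` (pre-lever locomotion, meters) and `epm` (active-lever
#'   entrances per meter).
#' @param sessions The target session labels; default Short Access 07-09.
#' @return Data frame, one row per subject: `subject_id`, `mean_loco`,
#'   `mean_epm`, `z_loco`, `z_epm`, `composite`, `group`, `n_sessions`.
#' @export
composite_prelever_zscore <- function(metrics,
                                      sessions = c("ShortAccess07",
                                                   "ShortAccess08",
                                                   "ShortAccess09")) {
  needed <- c("subject_id", "session_label", "loco_m", "epm")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols)) {
    pl_stop(paste0("metrics lacks columns: ",
                   paste(missing_cols, collapse = ", ")),
            "prelever_contract_error")
  }
  m <- metrics[metrics$session_label %in% sessions, needed]
  if (nrow(m) == 0L) {
    pl_stop("no rows in the target session window",
            "prelever_contract_error")
  }
  agg <- function(v) {
    tapply(v, m$subject_id, function(x) {
      x <- x[is.finite(x)]
      if (length(x)) mean(x) else NA_real_
    })
  }
  mean_loco <- agg(m$loco_m)
  mean_epm <- agg(m$epm)
  n_sessions <- as.integer(tapply(m$loco_m, m$subject_id, length))
  zscore <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      pl_stop("cohort has zero variance in a composite variable",
              "prelever_degenerate_cohort_error")
    }
    (v - mean(v, na.rm = TRUE)) / s
  }
  z_loco <- zscore(mean_loco)
  z_epm <- zscore(mean_epm)
  composite <- (z_loco + z_epm) / 2
  med <- median(composite, na.rm = TRUE)
  out <- data.frame(
    subject_id = names(mean_loco),
    mean_loco = as.numeric(mean_loco),
    mean_epm = as.numeric(mean_epm),
    z_loco = as.numeric(z_loco),
    z_epm = as.numeric(z_epm),
    composite = as.numeric(composite),
    group = ifelse(composite >= med, "High", "Low"),
    n_sessions = n_sessions,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Sensitization / tolerance labels from noncontingent drug locomotion
#'
#' Subjects whose locomotor response to the fixed noncontingent dose
#' increased from the first to the third drug session express psychomotor
#' sensitization; a decrease expresses tolerance. Values are
#' percent-of-baseline locomotion where the first drug session is the
#' baseline, so `delta` is the third session's percent change. An exact
#' zero change or a missing session leaves the subject Unclassified.
#'
#' @param drug_pct Data frame with columns `subject_id`, `drug01`, `drug03`
#'   (locomotion as percent difference from the Drug 01 baseline; `drug01`
#'   is 0 by construction but is accepted as stated for generality).
#' @return Data frame `subject_id`, `delta`, `label` with label in
#'   Sensitization / Tolerance / Unclassified.
#' @export
classify_expression <- function(drug_pct) {
  needed <- c("subject_id", "drug01", "drug03")
  missing_cols <- setdiff(needed, names(drug_pct))
  if (length(missing_cols)) {
    pl_stop(paste0("drug_pct lacks columns: ",
                   paste(missing_cols, collapse = ", ")),
            "prelever_contract_error")
  }
  delta <- drug_pct$drug03 - drug_pct$drug01
  label <- rep("Unclassified", length(delta))
  label[is.finite(delta) & delta > 0] <- "Sensitization"
  label[is.finite(delta) & delta < 0] <- "Tolerance"
  data.frame(subject_id = drug_pct$subject_id, delta = delta,
             label = label, stringsAsFactors = FALSE)
}

#' Categorical abstinence code between two sessions
#'
#' Abstinence is the time between the end of one session and the start of
#' the next. The study treats the codes as labels for consecutive days
#' (18 h), a two-day weekend (66 h), and a three-day weekend (90 h); the
#' elapsed interval maps to the nearest of those anchors within ±6 hours
#' (absorbing session-length and clock variation), anything else to
#' `"other"`.
#'
#' @param prev_end POSIXct end of the earlier session.
#' @param cur_start POSIXct start of the later session.
#' @return List with `hours` (numeric) and `category`
#'   (`"18"`, `"66"`, `"90"`, or `"other"`).
#' @export
encode_abstinence <- function(prev_end, cur_start) {
  hours <- as.numeric(difftime(cur_start, prev_end, units = "hours"))
  if (!is.finite(hours) || hours <= 0) {
    pl_stop("sessions out of order: non-positive abstinence interval",
            "prelever_manifest_error")
  }
  anchors <- c(18, 66, 90)
  d <- abs(hours - anchors)
  category <- if (min(d) <= 6) as.character(anchors[which.min(d)]) else "other"
  list(hours = hours, category = category)
}

#' Abstinence codes along one subject's manifest
#'
#' Back-to-back recordings (the Baseline/Saline/Drug phases of one
#' noncontingent session run contiguously) are not abstinence intervals
#' and are skipped; overlapping sessions are a manifest error.
#'
#' @param manifest Manifest rows for a single subject (see
#'   [read_manifest()]), any order; sorted by start time internally.
#' @return Data frame `session_label`, `hours`, `category`, one row per
#'   positive inter-session gap.
#' @export
abstinence_codes <- function(manifest) {
  manifest <- ensure_session_start(manifest)
  m <- manifest[order(manifest[["start"]]), ]
  empty <- data.frame(session_label = character(), hours = numeric(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(m) < 2L) return(empty)
  prev_end <- m[["start"]][-nrow(m)] + m$duration_h[-nrow(m)] * 3600
  gaps <- as.numeric(difftime(m[["start"]][-1L], prev_end,
                              units = "hours"))
  if (any(gaps < 0)) {
    pl_stop("overlapping sessions in manifest", "prelever_manifest_error")
  }
  keep <- which(gaps > 1e-9)
  if (!length(keep)) return(empty)
  codes <- Map(encode_abstinence, prev_end[keep],
               m[["start"]][-1L][keep])
  data.frame(session_label = m$session_label[-1L][keep],
             hours = vapply(codes, `[[`, numeric(1), "hours"),
             category = vapply(codes, `[[`, character(1), "category"),
             stringsAsFactors = FALSE)
}
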