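# The experimental timeline and operant-schedule arithmetic: session
# inventory, dosing constants, progressive-ratio requirements, breakpoints,
# and the footshock contingency.

#' Dosing configuration
#'
#' Defaults are the study constants: self-administration infusions of
#' 0.1 ml at 0.5 mg/kg pumped over 6 s followed by a 20 s timeout, and
#' noncontingent infusions of 0.3 ml at 1.5 mg/kg (three times the
#' self-administration dose).
#'
#' @param sa_dose,sa_volume,sa_pump_s,timeout_s Self-administration dose
#'   (mg/kg), volume (ml), pump duration (s), post-infusion timeout (s).
#' @param nc_dose,nc_volume Noncontingent dose (mg/kg) and volume (ml).
#' @return A `drug_config` list.
#' @export
drug_config <- function(sa_dose = 0.5, sa_volume = 0.1, sa_pump_s = 6,
                        timeout_s = 20, nc_dose = 1.5, nc_volume = 0.3) {
  vals <- c(sa_dose, sa_volume, sa_pump_s, timeout_s, nc_dose, nc_volume)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    pl_stop("all dosing constants must be positive",
            "prelever_domain_error")
  }
  structure(list(sa_dose = sa_dose, sa_volume = sa_volume,
                 sa_pump_s = sa_pump_s, timeout_s = timeout_s,
                 nc_dose = nc_dose, nc_volume = nc_volume),
            class = "drug_config")
}

#' Footshock configuration
#'
#' During the Shock session each infusion is paired with a footshock with
#' probability `pair_prob` (default 0.30; 0.3 mA for 0.5 s).
#'
#' @param pair_prob Pairing probability in \[0, 1\].
#' @param amp_mA Shock amplitude, milliamps.
#' @param dur_s Shock duration, seconds.
#' @return A `shock_config` list.
#' @export
shock_config <- function(pair_prob = 0.30, amp_mA = 0.3, dur_s = 0.5) {
  if (!is_scalar_number(pair_prob) || pair_prob < 0 || pair_prob > 1) {
    pl_stop("pair_prob must lie in [0, 1]", "prelever_domain_error")
  }
  structure(list(pair_prob = pair_prob, amp_mA = amp_mA, dur_s = dur_s),
            class = "shock_config")
}

#' Noncontingent-to-self-administration dose ratio
#'
#' @param cfg A [drug_config()].
#' @return `nc_dose / sa_dose` (3 at the defaults).
#' @export
dose_ratio <- function(cfg = drug_config()) {
  if (cfg$sa_dose <= 0) {
    pl_stop("sa_dose must be positive", "prelever_domain_error")
  }
  cfg$nc_dose / cfg$sa_dose
}

#' Progressive-ratio response requirement
#'
#' The continuous schedule is 5·exp(0.2·n) − 5 responses for the n-th
#' infusion; requirements are rounded to the nearest integer and floored at
#' one response so the first infusion is attainable (the printed curve
#' gives ≈1.11 at n = 1).
#'
#' @param injection_number Positive integer (vectorized).
#' @return Integer responses required.
#' @export
pr_requirement <- function(injection_number) {
  n <- injection_number
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    pl_stop("injection_number must be a positive integer",
            "prelever_domain_error")
  }
  pmax(1L, as.integer(round(5 * exp(0.2 * n) - 5)))
}

#' Breakpoint of a progressive-ratio session
#'
#' The last ratio completed before a 60-minute period without a completed
#' ratio. The lapse window is also checked between the final completion and
#' the session end (sessions normally terminate at the lapse, but simulated
#' or truncated logs may not); with no qualifying lapse the breakpoint is
#' the final completed ratio, and an empty session scores 0.
#'
#' @param events Data frame of infusion events with columns `time_s`
#'   (seconds from session start, sorted ascending) and `ratio_completed`.
#' @param session_len_s Session length in seconds.
#' @param lapse_s Lapse window in seconds (default 3600).
#' @return The breakpoint ratio (0 if no infusions).
#' @export
compute_breakpoint <- function(events, session_len_s, lapse_s = 3600) {
  if (is.null(events) || nrow(events) == 0L) return(0)
  t <- events$time_s
  if (is.unsorted(t)) {
    pl_stop("events must be time-sorted", "prelever_contract_error")
  }
  gaps <- diff(c(t, session_len_s))
  lapse <- which(gaps >= lapse_s)
  idx <- if (length(lapse)) lapse[1L] else length(t)
  events$ratio_completed[idx]
}

sa_session_types <- c("ShortAccess", "LongAccess", "Preshock", "Shock",
                      "ProgressiveRatio")
nc_session_types <- c("NoncontingentBaseline", "NoncontingentSaline",
                      "NoncontingentDrug")

session_duration_h <- c(ShortAccess = 2, LongAccess = 6, Preshock = 1,
                        Shock = 1, ProgressiveRatio = 6,
                        NoncontingentBaseline = 0.5,
                        NoncontingentSaline = 0.5, NoncontingentDrug = 0.5)

next_weekday <- function(date, holidays = as.Date(character())) {
  repeat {
    wd <- as.POSIXlt(date)$wday
    if (wd >= 1 && wd <= 5 && !(date %in% holidays)) return(date)
    date <- date + 1
  }
}

#' Canonical study timeline
#'
#' The 8-week Monday-Friday inventory: 10 Short Access, 15 Long Access,
#' one Preshock, one Shock, and three Progressive Ratio self-administration
#' sessions (30 total), interleaved with three noncontingent blocks of
#' Baseline/Saline/Drug phases (9 phases). Anchors: Noncontingent 01
#' precedes Short Access 01, Noncontingent 02 follows Short Access 09, and
#' Noncontingent 03 follows Long Access 14. One holiday Monday before the
#' Preshock week yields a three-day-weekend (90 h) gap alongside the
#' ordinary two-day-weekend (66 h) gaps.
#'
#' @param start_date First session date (a Monday; default 2023-01-02).
#' @param start_time Daily start clock time, `"HH:MM"` (default `"08:00"`).
#' @param frame_rate Video frame rate, used to place the lever-extension
#'   frame at the 15-minute mark of the 30-minute recording.
#' @return Data frame of session templates: `session_label`,
#'   `session_type`, `date`, `start_time`, `duration_h`,
#'   `lever_extension_frame` (NA for noncontingent phases), validated by
#'   [validate_timeline()].
#' @export
default_timeline <- function(start_date = as.Date("2023-01-02"),
                             start_time = "08:00", frame_rate = 10) {
  if (as.POSIXlt(start_date)$wday != 1L) {
    pl_stop("start_date must be a Monday", "prelever_domain_error")
  }
  day_plan <- c(
    "NC01",
    sprintf("ShortAccess%02d", 1:9),
    "NC02",
    "ShortAccess10",
    sprintf("LongAccess%02d", 1:14),
    "NC03",
    "LongAccess15",
    "Preshock01", "Shock01",
    sprintf("ProgressiveRatio%02d", 1:3)
  )
  n_days <- length(day_plan)
  schedule_dates <- function(holidays) {
    dates <- rep(start_date, n_days)
    d <- start_date - 1
    for (i in seq_len(n_days)) {
      d <- next_weekday(d + 1, holidays)
      dates[i] <- d
    }
    dates
  }
  # a holiday Monday ahead of the closing Preshock/Shock/PR week marks the
  # timeline's three-day weekend
  d0 <- schedule_dates(as.Date(character()))
  pre_date <- d0[match("Preshock01", day_plan)]
  holiday <- pre_date + (8 - as.POSIXlt(pre_date)$wday) %% 7
  dates <- schedule_dates(holiday)
  rows <- list()
  ext_frame <- as.integer(round(15 * 60 * frame_rate))
  start_min <- as.integer(substr(start_time, 4, 5)) +
    60L * as.integer(substr(start_time, 1, 2))
  for (i in seq_len(n_days)) {
    lab <- day_plan[i]
    if (grepl("^NC", lab)) {
      idx <- substr(lab, 3, 4)
      phases <- c("Baseline", "Saline", "Drug")
      types <- nc_session_types
      for (k in 1:3) {
        mins <- start_min + (k - 1L) * 30L
        rows[[length(rows) + 1L]] <- data.frame(
          session_label = paste0(phases[k], idx),
          session_type = types[k],
          date = as.character(dates[i]),
          start_time = sprintf("%02d:%02d", mins %/% 60L, mins %% 60L),
          duration_h = 0.5,
          lever_extension_frame = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    } else {
      type <- sub("[0-9]+$", "", lab)
      rows[[length(rows) + 1L]] <- data.frame(
        session_label = lab,
        session_type = type,
        date = as.character(dates[i]),
        start_time = start_time,
        duration_h = unname(session_duration_h[type]),
        lever_extension_frame = ext_frame,
        stringsAsFactors = FALSE
      )
    }
  }
  tl <- do.call(rbind, rows)
  validate_timeline(tl)
  tl
}

#' Validate a timeline's inventory invariants
#'
#' Checks the canonical counts (30 self-administration sessions, 9
#' noncontingent phases per subject), weekday-only scheduling, and that
#' lever-extension frames are present exactly on lever sessions.
#'
#' @param timeline A timeline data frame (see [default_timeline()]).
#' @return `timeline`, invisibly; raises on violation.
#' @export
validate_timeline <- function(timeline) {
  n_sa <- sum(timeline$session_type %in% sa_session_types)
  n_nc <- sum(timeline$session_type %in% nc_session_types)
  if (n_sa != 30L) {
    pl_stop(sprintf("timeline has %d self-administration sessions, not 30",
                    n_sa), "prelever_timeline_error")
  }
  if (n_nc != 9L) {
    pl_stop(sprintf("timeline has %d noncontingent phases, not 9", n_nc),
            "prelever_timeline_error")
  }
  wd <- as.POSIXlt(as.Date(timeline$date))$wday
  if (any(wd < 1 | wd > 5)) {
    pl_stop("timeline sessions must fall on Monday-Friday",
            "prelever_timeline_error")
  }
  sa <- timeline$session_type %in% sa_session_types
  if (any(is.na(timeline$lever_extension_frame[sa])) ||
      any(!is.na(timeline$lever_extension_frame[!sa]))) {
    pl_stop("lever_extension_frame must be present iff levers extend",
            "prelever_timeline_error")
  }
  invisible(timeline)
}
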