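DAYS_PER_YEAR <- 365.25
WEEK_DAYS <- 7
POST_TREATMENT_WINDOW_DAYS <- 28
CAP_52W_DAYS <- 52 * WEEK_DAYS + POST_TREATMENT_WINDOW_DAYS # 392

EVENT_CATEGORIES <- c("all_cause", "ssc_related", "er_or_icu", "icu",
                      "ventilation")

days_to_years <- function(d) d / DAYS_PER_YEAR
weeks_to_years <- function(w) w * WEEK_DAYS / DAYS_PER_YEAR

## ---- input validation helpers -------------------------------------------

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("fvcjoint_schema_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("fvcjoint_validation_error", "error")))
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_schema(what, ": missing mandatory column(s) ",
                paste(missing, collapse = ", "))
  }
}

bad_rows_msg <- function(rows, what, rule) {
  paste0(what, ": ", rule, " in row(s) ",
         paste(utils::head(rows, 10L), collapse = ", "),
         if (length(rows) > 10L) sprintf(" (and %d more)", length(rows) - 10L))
}

#' Read the three raw trial tables
#'
#' Reads the subject-level, visit-level and hospitalisation-event tables from
#' CSV and validates them: column presence, value ranges, duplicate visits,
#' orphan rows, and the requirement that every SSc-related hospitalisation is
#' also recorded as an all-cause hospitalisation.
#'
#' @param subjects_csv path to the subject table with columns `subject_id`,
#'   `arm` (1 = active treatment), `ata_positive`, `baseline_fvc_pct`,
#'   `followup_end_days` (end of the treatment period plus the 28-day
#'   post-treatment window), `death_day` (blank if the subject did not die).
#' @param visits_csv path to the visit table with columns `subject_id`,
#'   `visit_week`, `fvc_pct` (blank if the measurement is missing),
#'   `on_treatment`.
#' @param events_csv path to the hospitalisation-event table with columns
#'   `subject_id`, `event_day`, `category` (one of `all_cause`,
#'   `ssc_related`, `er_or_icu`, `icu`, `ventilation`); may be `NULL` when no
#'   hospitalisations occurred.
#' @return An object of class `fvc_trial`: a list with data frames
#'   `subjects`, `visits` and `events`.
#' @export
read_tables <- function(subjects_csv, visits_csv, events_csv = NULL) {
  for (p in c(subjects_csv, visits_csv, events_csv)) {
    if (!file.exists(p)) stop_schema("file not found: ", p)
  }
  subjects <- utils::read.csv(subjects_csv, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_csv, stringsAsFactors = FALSE)
  events <- if (is.null(events_csv)) {
    data.frame(subject_id = character(0), event_day = numeric(0),
               category = character(0), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(events_csv, stringsAsFactors = FALSE)
  }
  fvc_trial(subjects, visits, events)
}

#' Assemble and validate a trial object from in-memory tables
#'
#' @param subjects,visits,events data frames with the columns documented in
#'   [read_tables()].
#' @return An object of class `fvc_trial`.
#' @export
fvc_trial <- function(subjects, visits, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(subject_id = character(0), event_day = numeric(0),
                         category = character(0), stringsAsFactors = FALSE)
  }
  check_columns(subjects, c("subject_id", "arm", "ata_positive",
                            "baseline_fvc_pct", "followup_end_days"),
                "subjects")
  if (!"death_day" %in% names(subjects)) subjects$death_day <- NA_real_
  check_columns(visits, c("subject_id", "visit_week", "fvc_pct",
                          "on_treatment"), "visits")
  check_columns(events, c("subject_id", "event_day", "category"), "events")

  subjects$subject_id <- as.character(subjects$subject_id)
  visits$subject_id <- as.character(visits$subject_id)
  events$subject_id <- as.character(events$subject_id)
  for (col in c("arm", "ata_positive", "baseline_fvc_pct",
                "followup_end_days", "death_day")) {
    subjects[[col]] <- suppressWarnings(as.numeric(subjects[[col]]))
  }
  for (col in c("visit_week", "fvc_pct", "on_treatment")) {
    visits[[col]] <- suppressWarnings(as.numeric(visits[[col]]))
  }
  events$event_day <- suppressWarnings(as.numeric(events$event_day))

  dup <- duplicated(subjects$subject_id)
  if (any(dup)) {
    stop_validation(bad_rows_msg(which(dup), "subjects",
                                 "duplicate subject_id"))
  }
  bad <- which(!(subjects$arm %in% c(0, 1)))
  if (length(bad)) stop_validation(bad_rows_msg(bad, "subjects",
                                                "arm must be 0 or 1"))
  bad <- which(!(subjects$ata_positive %in% c(0, 1)))
  if (length(bad)) stop_validation(bad_rows_msg(bad, "subjects",
                                                "ata_positive must be 0 or 1"))
  bad <- which(!is.finite(subjects$baseline_fvc_pct) |
                 subjects$baseline_fvc_pct <= 0)
  if (length(bad)) stop_validation(bad_rows_msg(bad, "subjects",
                                                "baseline_fvc_pct must be > 0"))
  bad <- which(!is.finite(subjects$followup_end_days) |
                 subjects$followup_end_days <= 0)
  if (length(bad)) {
    stop_validation(bad_rows_msg(bad, "subjects",
                                 "followup_end_days must be > 0"))
  }
  bad <- which(!is.na(subjects$death_day) & subjects$death_day < 0)
  if (length(bad)) stop_validation(bad_rows_msg(bad, "subjects",
                                                "death_day must be >= 0"))

  bad <- which(!is.finite(visits$visit_week) | visits$visit_week < 0)
  if (length(bad)) stop_validation(bad_rows_msg(bad, "visits",
                                                "visit_week must be >= 0"))
  bad <- which(!is.na(visits$fvc_pct) & visits$fvc_pct <= 0)
  if (length(bad)) stop_validation(bad_rows_msg(bad, "visits",
                                                "fvc_pct must be > 0"))
  bad <- which(!(visits$on_treatment %in% c(0, 1)))
  if (length(bad)) stop_validation(bad_rows_msg(bad, "visits",
                                                "on_treatment must be 0 or 1"))
  dup <- duplicated(visits[c("subject_id", "visit_week")])
  if (any(dup)) {
    stop_validation(bad_rows_msg(which(dup), "visits",
                                 "duplicate (subject_id, visit_week)"))
  }
  orphan <- which(!(visits$subject_id %in% subjects$subject_id))
  if (length(orphan)) stop_validation(bad_rows_msg(orphan, "visits",
                                                   "unknown subject_id"))

  bad <- which(!is.finite(events$event_day) | events$event_day < 0)
  if (length(bad)) stop_validation(bad_rows_msg(bad, "events",
                                                "event_day must be >= 0"))
  bad <- which(!(events$category %in% EVENT_CATEGORIES))
  if (length(bad)) {
    stop_validation(bad_rows_msg(bad, "events", paste0(
      "category must be one of ", paste(EVENT_CATEGORIES, collapse = ", "))))
  }
  orphan <- which(!(events$subject_id %in% subjects$subject_id))
  if (length(orphan)) stop_validation(bad_rows_msg(orphan, "events",
                                                   "unknown subject_id"))
  # every ssc_related hospitalisation must also be recorded as all_cause
  ssc <- events[events$category == "ssc_related", ]
  if (nrow(ssc)) {
    ac <- events[events$category == "all_cause", ]
    key_ssc <- paste(ssc$subject_id, ssc$event_day)
    key_ac <- paste(ac$subject_id, ac$event_day)
    bad <- which(!(key_ssc %in% key_ac))
    if (length(bad)) {
      stop_validation(bad_rows_msg(
        which(events$category == "ssc_related")[bad], "events",
        "ssc_related event without matching all_cause record"))
    }
  }

  structure(list(subjects = subjects, visits = visits, events = events),
            class = "fvc_trial")
}

#' @export
print.fvc_trial <- function(x, ...) {
  cat("Trial data:", nrow(x$subjects), "subjects,",
      nrow(x$visits), "visits,",
      nrow(x$events), "hospitalisation-event records\n")
  invisible(x)
}

#' Write the trial tables back to CSV
#'
#' Inverse of [read_tables()]; the round trip reproduces the input up to
#' column order.
#'
#' @param trial an `fvc_trial` object.
#' @param subjects_csv,visits_csv,events_csv output paths.
#' @return The paths, invisibly.
#' @export
write_tables <- function(trial, subjects_csv, visits_csv, events_csv) {
  stopifnot(inherits(trial, "fvc_trial"))
  utils::write.csv(trial$subjects, subjects_csv, row.names = FALSE, na = "")
  utils::write.csv(trial$visits, visits_csv, row.names = FALSE, na = "")
  utils::write.csv(trial$events, events_csv, row.names = FALSE, na = "")
  invisible(c(subjects_csv, visits_csv, events_csv))
}

## ---- endpoint derivation -------------------------------------------------

period_cap_days <- function(period) {
  switch(match.arg(period, c("52w", "whole")),
         "52w" = CAP_52W_DAYS,
         "whole" = Inf)
}

#' Derive the composite time-to-first-event endpoint
#'
#' For each subject, the event time is the first qualifying hospitalisation
#' (of the requested category) or death, whichever comes first, provided it
#' falls within the follow-up window (treatment period plus 28 days) and the
#' analysis period; otherwise the subject is censored at the end of follow-up
#' capped by the analysis period.  Hospitalisations after the follow-up
#' window do not qualify.  Days are converted to years (days/365.25).  An
#' event on day 0 is shifted to half a day to keep event times positive.
#'
#' @param trial an `fvc_trial` object.
#' @param endpoint hospitalisation category defining the composite; one of
#'   `"all_cause"`, `"ssc_related"`, `"er_or_icu"`, `"icu"`, `"ventilation"`.
#' @param period analysis period: `"52w"` (capped at 52 weeks of treatment
#'   plus the 28-day window, i.e. 392 days) or `"whole"` (whole trial).
#' @return A data frame with one row per subject: `subject_id`,
#'   `event_time_years`, `event` (1 = composite event observed).
#' @export
derive_endpoint <- function(trial, endpoint = "all_cause", period = "52w") {
  stopifnot(inherits(trial, "fvc_trial"))
  endpoint <- match.arg(endpoint, EVENT_CATEGORIES)
  cap <- period_cap_days(period)
  subs <- trial$subjects
  ev <- trial$events[trial$events$category == endpoint, , drop = FALSE]

  first_hosp <- rep(Inf, nrow(subs))
  if (nrow(ev)) {
    agg <- tapply(ev$event_day, ev$subject_id, min)
    idx <- match(names(agg), subs$subject_id)
    first_hosp[idx] <- as.numeric(agg)
  }
  death <- ifelse(is.na(subs$death_day), Inf, subs$death_day)
  censor_day <- pmin(subs$followup_end_days, cap)
  # events outside the subject's follow-up window never qualify
  first_hosp[first_hosp > subs$followup_end_days] <- Inf
  death[death > subs$followup_end_days] <- Inf
  first_ev <- pmin(first_hosp, death)

  is_event <- first_ev <= censor_day
  t_day <- ifelse(is_event, first_ev, censor_day)
  t_day[t_day <= 0] <- 0.5
  data.frame(subject_id = subs$subject_id,
             event_time_years = days_to_years(t_day),
             event = as.integer(is_event),
             stringsAsFactors = FALSE)
}

#' Retain the on-treatment FVC measurements preceding the event
#'
#' Keeps visits that are on treatment, have a non-missing FVC value, occurred
#' strictly before the subject's event or censoring time, and are
#' post-baseline (the week-0 measurement enters the model only as a
#' covariate).
#'
#' @param visits the visit data frame of an `fvc_trial`.
#' @param endpoints the per-subject endpoint frame from [derive_endpoint()].
#' @return A data frame `subject_id`, `time_years`, `fvc_pct` of retained
#'   measurements.
#' @export
filter_on_treatment <- function(visits, endpoints) {
  ty <- weeks_to_years(visits$visit_week)
  limit <- endpoints$event_time_years[match(visits$subject_id,
                                            endpoints$subject_id)]
  keep <- visits$on_treatment == 1 &
    !is.na(visits$fvc_pct) &
    visits$visit_week > 0 &
    !is.na(limit) & ty < limit
  out <- data.frame(subject_id = visits$subject_id[keep],
                    time_years = ty[keep],
                    fvc_pct = visits$fvc_pct[keep],
                    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$time_years), , drop = FALSE]
}

#' Build the analysis dataset for a joint model
#'
#' Applies [derive_endpoint()] and [filter_on_treatment()] and packages the
#' result: one row per subject with covariates and survival outcome, plus the
#' retained longitudinal FVC measurements.  Subjects with no retained
#' measurements are kept; they still contribute survival information.
#'
#' @inheritParams derive_endpoint
#' @return An object of class `jm_data`: a list with elements `subjects`
#'   (covariates, `event_time_years`, `event`, `n_obs`), `long` (retained
#'   measurements), `endpoint`, `period`, `n`, `n_events` and `unfittable`
#'   (`TRUE` when no events were observed).
#' @export
build_joint_dataset <- function(trial, endpoint = "all_cause",
                                period = "52w") {
  endpoint <- match.arg(endpoint, EVENT_CATEGORIES)
  period <- match.arg(period, c("52w", "whole"))
  ep <- derive_endpoint(trial, endpoint, period)
  long <- filter_on_treatment(trial$visits, ep)

  subs <- trial$subjects
  idx <- match(subs$subject_id, ep$subject_id)
  out_sub <- data.frame(subject_id = subs$subject_id,
                        arm = as.integer(subs$arm),
                        ata_positive = as.integer(subs$ata_positive),
                        baseline_fvc_pct = subs$baseline_fvc_pct,
                        event_time_years = ep$event_time_years[idx],
                        event = ep$event[idx],
                        stringsAsFactors = FALSE)
  out_sub$n_obs <- as.integer(table(factor(long$subject_id,
                                           levels = subs$subject_id)))
  n_events <- sum(out_sub$event)
  structure(list(subjects = out_sub, long = long,
                 endpoint = endpoint, period = period,
                 n = nrow(out_sub), n_events = n_events,
                 unfittable = n_events == 0L),
            class = "jm_data")
}

#' @export
print.jm_data <- function(x, ...) {
  cat(sprintf(
    "Joint-model dataset: endpoint %s, period %s\n  %d subjects, %d with event (%.1f%%), %d FVC measurements\n",
    x$endpoint, x$period, x$n, x$n_events, 100 * x$n_events / max(x$n, 1),
    nrow(x$long)))
  if (x$unfittable) cat("  NOTE: no events observed; endpoint unfittable\n")
  invisible(x)
}

#' @export
summary.jm_data <- function(object, ...) {
  s <- object$subjects
  out <- list(endpoint = object$endpoint, period = object$period,
              n = object$n, n_events = object$n_events,
              pct_events = 100 * object$n_events / max(object$n, 1),
              n_measurements = nrow(object$long),
              median_followup_years = stats::median(s$event_time_years),
              unfittable = object$unfittable)
  class(out) <- "summary.jm_data"
  out
}

#' @export
print.summary.jm_data <- function(x, ...) {
  cat(sprintf("endpoint: %s (%s)\n", x$endpoint, x$period))
  cat(sprintf("subjects: %d; events: %d (%.1f%%); measurements: %d\n",
              x$n, x$n_events, x$pct_events, x$n_measurements))
  cat(sprintf("median follow-up: %.2f years\n", x$median_followup_years))
  invisible(x)
}
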