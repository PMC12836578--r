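# Triage scoring: grades -> severity buckets -> green/orange/red, plus the
# alert-deadline, reminder, and monthly-call scheduling that surrounds it.

#' Bucket a symptom grade into absent/slight, moderate, or severe
#'
#' Default mapping: grade 0--1 is `absent_slight`, grade 2 `moderate`,
#' grade 3--4 `severe`. If the policy carries an escalation override for
#' the item at or below the grade, the response is bucketed `severe`
#' regardless of the default mapping.
#'
#' @param grade Integer grade(s), within the item ceiling.
#' @param item_id Item identifier(s), recycled against `grade`.
#' @param policy A [scoring_policy()].
#' @return Character vector in `{"absent_slight", "moderate", "severe"}`.
#' @examples
#' bucket_grade(2, "diarrhea")
#' bucket_grade(2, "diarrhea", scoring_policy(escalation_overrides = c(diarrhea = 2)))
#' @export
bucket_grade <- function(grade, item_id, policy = scoring_policy()) {
  unknown <- setdiff(unique(item_id), policy$item_set$item_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown item_id: ", toString(unknown)),
      class = "eprotriage_validation_error"
    )
  }
  out <- ifelse(grade >= 3, "severe", ifelse(grade == 2, "moderate", "absent_slight"))
  ov <- policy$escalation_overrides
  if (length(ov) > 0) {
    thr <- ov[as.character(item_id)]
    out[!is.na(thr) & grade >= thr] <- "severe"
  }
  out
}

triage_colors <- function() factor(character(0), levels = c("green", "orange", "red"))

color_from_counts <- function(n_moderate, n_severe) {
  factor(
    ifelse(n_severe >= 1 | n_moderate >= 3, "red",
      ifelse(n_moderate >= 1, "orange", "green")
    ),
    levels = c("green", "orange", "red")
  )
}

#' Score questionnaires green/orange/red
#'
#' Applies the triage rule: green if every symptom is absent/slight;
#' orange if one or two symptoms are moderate and none severe; red if at
#' least one symptom is severe or three or more are moderate. The rule is
#' total and deterministic — every questionnaire gets exactly one color.
#'
#' @param questionnaires Wide questionnaire tibble (validated).
#' @param policy A [scoring_policy()]; escalation overrides are applied at
#'   the bucketing step.
#' @return A tibble with one row per questionnaire: `questionnaire_id`,
#'   `patient_id`, `completed_at`, `color` (ordered factor
#'   green < orange < red), `n_moderate`, `n_severe`.
#' @examples
#' q <- empty_questionnaire("P1", "Q1", as.POSIXct("2021-01-04 10:00", tz = "UTC"))
#' q$fatigue <- 2L
#' score_questionnaires(q)
#' @export
score_questionnaires <- function(questionnaires, policy = scoring_policy()) {
  validate_questionnaires(questionnaires, policy$item_set)
  items <- policy$item_set$item_id
  n <- nrow(questionnaires)
  n_moderate <- integer(n)
  n_severe <- integer(n)
  for (id in items) {
    b <- bucket_grade(questionnaires[[id]], id, policy)
    n_moderate <- n_moderate + (b == "moderate")
    n_severe <- n_severe + (b == "severe")
  }
  tibble::tibble(
    questionnaire_id = questionnaires$questionnaire_id,
    patient_id = questionnaires$patient_id,
    completed_at = questionnaires$completed_at,
    color = color_from_counts(n_moderate, n_severe),
    n_moderate = as.integer(n_moderate),
    n_severe = as.integer(n_severe)
  )
}

#' @rdname score_questionnaires
#' @param questionnaire A one-row questionnaire tibble.
#' @export
score_questionnaire <- function(questionnaire, policy = scoring_policy()) {
  score_questionnaires(questionnaire, policy)
}

parse_hhmm <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] * 3600 + parts[2] * 60
}

#' Shift a timestamp to the next working-hours opening
#'
#' Alerts are handled during working hours only (default 09:00--16:30).
#' A questionnaire received outside that window is treated as received at
#' the next opening: same day 09:00 if before opening, next day 09:00 if
#' after close (skipping weekends when the policy says so).
#'
#' @param at POSIXct timestamp(s).
#' @param policy A [scoring_policy()] supplying the window.
#' @return POSIXct of the same length.
#' @export
effective_receipt <- function(at, policy = scoring_policy()) {
  open_s <- parse_hhmm(policy$working_hours[1])
  close_s <- parse_hhmm(policy$working_hours[2])
  day <- as.POSIXct(trunc(at, "days"))
  sec <- as.numeric(at) - as.numeric(day)
  out <- at
  before <- sec < open_s
  after <- sec >= close_s
  out[before] <- day[before] + open_s
  out[after] <- day[after] + 86400 + open_s
  if (policy$weekend_closed) {
    repeat {
      wd <- as.POSIXlt(out)$wday
      on_weekend <- wd %in% c(0, 6)
      if (!any(on_weekend)) break
      d <- as.POSIXct(trunc(out[on_weekend], "days"))
      out[on_weekend] <- d + 86400 + open_s
    }
  }
  out
}

#' Raise alerts from triage scores
#'
#' Green scores raise nothing. An orange score must be answered within
#' 24--48 h of effective receipt; a red score immediately (earliest
#' response time equals effective receipt). Effective receipt is the
#' questionnaire timestamp moved into working hours by
#' [effective_receipt()].
#'
#' @param scores Tibble from [score_questionnaires()] (needs
#'   `questionnaire_id`, `color`, `completed_at`).
#' @param policy A [scoring_policy()].
#' @return A tibble of alerts: `questionnaire_id`, `color`, `raised_at`
#'   (effective receipt), `respond_by_earliest`, `respond_by_latest`.
#'   Zero rows if all scores are green.
#' @export
raise_alerts <- function(scores, policy = scoring_policy()) {
  al <- dplyr::filter(scores, color != "green")
  eff <- effective_receipt(al$completed_at, policy)
  is_red <- al$color == "red"
  tibble::tibble(
    questionnaire_id = al$questionnaire_id,
    color = al$color,
    raised_at = eff,
    respond_by_earliest = dplyr::if_else(is_red, eff, eff + 24 * 3600),
    respond_by_latest = dplyr::if_else(is_red, eff, eff + 48 * 3600)
  )
}

#' @rdname raise_alerts
#' @param score A one-row score tibble.
#' @return `raise_alert()` returns a one-row alert tibble, or `NULL` for a
#'   green score.
#' @export
raise_alert <- function(score, policy = scoring_policy()) {
  out <- raise_alerts(score, policy)
  if (nrow(out) == 0) NULL else out
}

#' Reminder schedule for an unanswered invitation
#'
#' A reminder is sent 7 days (configurable) after the invitation if the
#' questionnaire has not been completed, and repeats every period until
#' completion or the end of the observation window.
#'
#' @param invited_at Invitation timestamp (POSIXct).
#' @param completed_at Completion timestamp, or `NULL`/`NA` if never
#'   completed.
#' @param until End of the observation window; required when
#'   `completed_at` is missing.
#' @param period_days Days between reminders, default 7.
#' @param max_reminders Cap on the number of reminders, default `Inf`.
#' @return POSIXct vector of reminder times (possibly empty).
#' @examples
#' t0 <- as.POSIXct("2021-01-04 09:00", tz = "UTC")
#' reminder_schedule(t0, completed_at = t0 + 2 * 86400)
#' reminder_schedule(t0, until = t0 + 16 * 86400)
#' @export
reminder_schedule <- function(invited_at, completed_at = NULL, until = NULL,
                              period_days = 7, max_reminders = Inf) {
  cutoff <- if (!is.null(completed_at) && !is.na(completed_at)) {
    completed_at
  } else if (!is.null(until)) {
    until
  } else {
    abort("need completed_at or until to bound the reminder schedule")
  }
  out <- numeric(0)
  k <- 1
  while (k <= max_reminders) {
    t_k <- invited_at + k * period_days * 86400
    if (t_k > cutoff) break
    out <- c(out, as.numeric(t_k))
    k <- k + 1
  }
  as.POSIXct(out, origin = "1970-01-01", tz = attr(invited_at, "tzone") %||% "UTC")
}

#' Monthly nurse-call schedule
#'
#' Independent of alerts, the oncology nurse calls each patient once a
#' month. The schedule is one call per 28-day period from enrollment,
#' truncated at the end of follow-up (a calendar-month anchor would make
#' call dates depend on month lengths; the 28-day grid is deterministic).
#'
#' @param enrolled_at,end_at Dates bounding follow-up.
#' @param period_days Days between calls, default 28.
#' @return Date vector of call dates (possibly empty).
#' @examples
#' monthly_call_schedule(as.Date("2021-01-01"), as.Date("2021-04-01"))
#' @export
monthly_call_schedule <- function(enrolled_at, end_at, period_days = 28) {
  stopifnot(enrolled_at <= end_at)
  out <- seq(enrolled_at + period_days, by = period_days, length.out = 1000)
  out[out <= end_at]
}
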