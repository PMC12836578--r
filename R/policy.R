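# Scoring policy: item set, escalation overrides, workflow timing knobs.

#' Construct a triage scoring policy
#'
#' A policy bundles everything configurable about scoring and alert
#' handling. With no escalation overrides it reproduces the instrument's
#' published rule exactly: a symptom is absent/slight at grade 0--1,
#' moderate at grade 2, severe at grade 3--4. An escalation override maps
#' an item to the minimum grade that is force-bucketed severe, e.g.
#' `c(diarrhea = 2)` turns any grade-2 diarrhea report into a red score —
#' the variant proposed for better colitis capture. Overrides act at the
#' bucketing step, not by recoloring, so moderate/severe counts stay
#' meaningful.
#'
#' @param item_set Item table, default [standard_item_set()].
#' @param escalation_overrides Named integer vector `item_id -> min grade`
#'   bucketed severe. Default empty.
#' @param working_hours Length-2 character `c(start, end)` as "HH:MM";
#'   alerts received outside this window are timestamped at the next
#'   opening. Default `c("09:00", "16:30")`.
#' @param weekend_closed If `TRUE`, Saturday/Sunday are skipped when
#'   finding the next opening. Default `FALSE` (monitoring runs every day).
#' @param reminder_period_days Days between completion reminders, default 7.
#' @param max_reminders Maximum reminders per invitation, default `Inf`.
#' @return A list of class `scoring_policy`.
#' @examples
#' scoring_policy()
#' scoring_policy(escalation_overrides = c(diarrhea = 2))
#' @export
scoring_policy <- function(item_set = standard_item_set(),
                           escalation_overrides = integer(0),
                           working_hours = c("09:00", "16:30"),
                           weekend_closed = FALSE,
                           reminder_period_days = 7,
                           max_reminders = Inf) {
  if (length(escalation_overrides) > 0) {
    if (is.null(names(escalation_overrides)) || any(names(escalation_overrides) == "")) {
      abort("escalation_overrides must be a named vector",
        class = "eprotriage_validation_error"
      )
    }
    unknown <- setdiff(names(escalation_overrides), item_set$item_id)
    if (length(unknown) > 0) {
      abort(paste0("escalation override for unknown item: ", toString(unknown)),
        class = "eprotriage_validation_error"
      )
    }
  }
  stopifnot(length(working_hours) == 2, reminder_period_days > 0)
  structure(
    list(
      item_set = item_set,
      escalation_overrides = escalation_overrides,
      working_hours = working_hours,
      weekend_closed = isTRUE(weekend_closed),
      reminder_period_days = reminder_period_days,
      max_reminders = max_reminders
    ),
    class = "scoring_policy"
  )
}

#' @export
print.scoring_policy <- function(x, ...) {
  cat("<scoring_policy>\n")
  cat("  items:", nrow(x$item_set), "\n")
  if (length(x$escalation_overrides) > 0) {
    cat(
      "  escalation overrides:",
      paste0(names(x$escalation_overrides), ">=", x$escalation_overrides,
        collapse = ", "
      ), "\n"
    )
  } else {
    cat("  escalation overrides: none (published rule)\n")
  }
  cat("  working hours:", x$working_hours[1], "-", x$working_hours[2], "\n")
  invisible(x)
}

#' Read or write a scoring policy as YAML
#'
#' The file carries per-item ceilings, escalation overrides, the
#' working-hours window and the reminder period, so a policy variant is a
#' configuration artifact rather than code.
#'
#' @param path File path.
#' @param policy A `scoring_policy`.
#' @return `read_policy()` returns a `scoring_policy`; `write_policy()`
#'   returns `path` invisibly.
#' @export
read_policy <- function(path) {
  raw <- yaml::read_yaml(path)
  item_set <- symptom_item_set(
    max_grades = unlist(raw$max_grades %||% list())
  )
  scoring_policy(
    item_set = item_set,
    escalation_overrides = unlist(raw$escalation_overrides %||% list()),
    working_hours = unlist(raw$working_hours %||% c("09:00", "16:30")),
    weekend_closed = isTRUE(raw$weekend_closed),
    reminder_period_days = raw$reminder_period_days %||% 7,
    max_reminders = raw$max_reminders %||% Inf
  )
}

#' @rdname read_policy
#' @export
write_policy <- function(policy, path) {
  out <- list(
    max_grades = as.list(setNames(
      as.integer(policy$item_set$max_grade), policy$item_set$item_id
    )),
    escalation_overrides = as.list(policy$escalation_overrides),
    working_hours = as.list(policy$working_hours),
    weekend_closed = policy$weekend_closed,
    reminder_period_days = policy$reminder_period_days
  )
  if (is.finite(policy$max_reminders)) out$max_reminders <- policy$max_reminders
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
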