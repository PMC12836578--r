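# Structured evaluation report over a cohort bundle.

#' Evaluate a cohort end-to-end
#'
#' Scores every questionnaire, raises alerts, links them to grade >=2
#' IrAEs, and assembles the full retrospective evaluation: score
#' distribution and alert rate, per-event detection table, diagnostic
#' metrics over all events and over symptomatic ones, miss-reason tally,
#' false-alert cause summary (when annotations exist), and the time-saved
#' summary against the visit schedule.
#'
#' @param bundle A [cohort_bundle()].
#' @param policy A [scoring_policy()].
#' @param window_days Linkage window in days, default 30.
#' @param relatedness Category-to-item map, default [default_relatedness()].
#' @param level Confidence level for metric intervals.
#' @param ci_method `"wilson"` or `"exact"`.
#' @return A list of class `cohort_report`; see the print method for the
#'   rendered layout.
#' @examples
#' b <- simulate_cohort(simulation_params(n_patients = 30, seed = 7))
#' cohort_report(b)
#' @export
cohort_report <- function(bundle, policy = scoring_policy(), window_days = 30,
                          relatedness = default_relatedness(), level = 0.95,
                          ci_method = c("wilson", "exact")) {
  ci_method <- match.arg(ci_method)
  n_q <- nrow(bundle$questionnaires)
  if (n_q == 0) {
    return(structure(
      list(
        n_patients = nrow(bundle$patients), n_questionnaires = 0,
        score_distribution = tibble::tibble(
          color = factor(c("green", "orange", "red"),
            levels = c("green", "orange", "red")
          ),
          n = c(0L, 0L, 0L), proportion = c(NA_real_, NA_real_, NA_real_)
        ),
        alert_rate = NA_real_, labels = NULL, links = NULL,
        label_tally = NULL, metrics_all = NULL, metrics_symptomatic = NULL,
        miss_reasons = NULL, cause_summary = NULL, time_saved = NULL,
        window_days = window_days
      ),
      class = "cohort_report"
    ))
  }
  scores <- score_questionnaires(bundle$questionnaires, policy)
  linkage <- link_detections(bundle$questionnaires, bundle$iraes,
    policy = policy, window_days = window_days, relatedness = relatedness
  )
  links <- add_time_saved(linkage, bundle$questionnaires, bundle$visits)

  dist <- scores |>
    dplyr::count(color, .drop = FALSE) |>
    dplyr::mutate(proportion = n / n_q)
  alert_rate <- sum(dist$n[dist$color != "green"]) / n_q

  cc_all <- confusion_counts(linkage, symptomatic_only = FALSE)
  cc_sym <- confusion_counts(linkage, symptomatic_only = TRUE)
  metrics_all <- diagnostic_metrics(cc_all, level, ci_method)
  metrics_sym <- diagnostic_metrics(cc_sym, level, ci_method)

  miss <- links |>
    dplyr::filter(!is.na(miss_reason)) |>
    dplyr::count(miss_reason)

  causes <- NULL
  if (!is.null(bundle$ground_truth) && "gt_cause" %in% names(bundle$ground_truth)) {
    ann <- bundle$ground_truth |>
      dplyr::filter(!is.na(gt_cause)) |>
      dplyr::select(questionnaire_id, cause = gt_cause)
    # only summarize if every false alert is annotated; a simulated cohort
    # may contain emergent false alerts (e.g. a signature for one event
    # qualifying for none), which carry no generating cause
    false_ids <- linkage$labels$questionnaire_id[linkage$labels$label == "alert_false"]
    if (all(false_ids %in% ann$questionnaire_id)) {
      causes <- cause_summary(linkage$labels, ann)
    }
  }

  ts <- links$days_saved[!is.na(links$days_saved)]
  ts_summary <- if (length(ts) > 0) {
    tibble::tibble(
      n = length(ts), mean = mean(ts), median = stats::median(ts),
      min = min(ts), max = max(ts)
    )
  } else {
    NULL
  }
  lead <- links$lead_days[!is.na(links$lead_days)]
  lead_summary <- if (length(lead) > 0) {
    tibble::tibble(
      n = length(lead), mean = mean(lead), median = stats::median(lead),
      min = min(lead), max = max(lead)
    )
  } else {
    NULL
  }

  structure(
    list(
      n_patients = nrow(bundle$patients), n_questionnaires = n_q,
      score_distribution = dist, alert_rate = alert_rate,
      labels = linkage$labels,
      label_tally = dplyr::count(linkage$labels, label),
      links = links,
      confusion_all = cc_all, confusion_symptomatic = cc_sym,
      metrics_all = metrics_all, metrics_symptomatic = metrics_sym,
      miss_reasons = miss, cause_summary = causes,
      time_saved = ts_summary, lead_time = lead_summary,
      window_days = window_days
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Cohort evaluation report ==\n")
  cat(
    x$n_patients, "patients,", x$n_questionnaires, "questionnaires;",
    "linkage window", x$window_days, "days\n\n"
  )
  if (x$n_questionnaires == 0) {
    cat("(empty cohort)\n")
    return(invisible(x))
  }
  cat("Score distribution:\n")
  print(as.data.frame(x$score_distribution), row.names = FALSE)
  cat(sprintf("Alert rate: %.1f%%\n\n", 100 * x$alert_rate))
  cat("Questionnaire labels:\n")
  print(as.data.frame(x$label_tally), row.names = FALSE)
  fmt <- function(m) {
    for (i in seq_len(nrow(m))) {
      cat(sprintf(
        "  %-12s %5.1f%% (%d/%d, %d%% CI %.1f-%.1f%%)\n",
        m$name[i], 100 * m$point[i], m$numerator[i], m$denominator[i],
        round(100 * m$level[i]), 100 * m$ci_low[i], 100 * m$ci_high[i]
      ))
    }
  }
  cat("\nDiagnostic metrics, all grade >=2 IrAEs:\n")
  fmt(x$metrics_all)
  cat("Diagnostic metrics, symptomatic IrAEs only:\n")
  fmt(x$metrics_symptomatic)
  if (!is.null(x$miss_reasons) && nrow(x$miss_reasons) > 0) {
    cat("\nReasons for missed IrAEs:\n")
    print(as.data.frame(x$miss_reasons), row.names = FALSE)
  }
  if (!is.null(x$cause_summary) && nrow(x$cause_summary) > 0) {
    cat("\nFalse-alert causes:\n")
    print(as.data.frame(x$cause_summary), row.names = FALSE)
  }
  if (!is.null(x$time_saved)) {
    cat(sprintf(
      "\nDays saved vs next visit (n=%d): mean %.1f, median %.1f, range %d-%d\n",
      x$time_saved$n, x$time_saved$mean, x$time_saved$median,
      x$time_saved$min, x$time_saved$max
    ))
  }
  invisible(x)
}

#' Serialize a cohort report
#'
#' `report_to_json()` writes the full report as one JSON document;
#' `report_tables()` returns the report's tabular pieces as a named list
#' of tibbles, which `write_report_tables()` renders as TSV files.
#'
#' @param report A `cohort_report`.
#' @param path Output JSON file.
#' @param dir Output directory for TSV tables.
#' @return `report_to_json()`/`write_report_tables()` return their output
#'   location invisibly; `report_tables()` a named list of tibbles.
#' @export
report_to_json <- function(report, path) {
  payload <- list(
    n_patients = report$n_patients,
    n_questionnaires = report$n_questionnaires,
    alert_rate = report$alert_rate,
    window_days = report$window_days,
    score_distribution = report$score_distribution,
    label_tally = report$label_tally,
    metrics_all = report$metrics_all,
    metrics_symptomatic = report$metrics_symptomatic,
    miss_reasons = report$miss_reasons,
    cause_summary = report$cause_summary,
    time_saved = report$time_saved,
    lead_time = report$lead_time,
    detections = report$links
  )
  jsonlite::write_json(payload, path,
    dataframe = "rows", na = "null", auto_unbox = TRUE,
    POSIXt = "ISO8601", Date = "ISO8601", digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_tables <- function(report) {
  out <- list(
    score_distribution = report$score_distribution,
    label_tally = report$label_tally,
    metrics_all = report$metrics_all,
    metrics_symptomatic = report$metrics_symptomatic,
    miss_reasons = report$miss_reasons,
    cause_summary = report$cause_summary,
    detections = report$links
  )
  Filter(Negate(is.null), out)
}

#' @rdname report_to_json
#' @export
write_report_tables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- report_tables(report)
  for (nm in names(tabs)) {
    readr::write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")), na = "")
  }
  invisible(dir)
}
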