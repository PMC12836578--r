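# Packaged aggregate counts from the development cohort, so the headline
# evaluation numbers are reproducible offline without patient-level data.

#' Aggregate counts of the development cohort
#'
#' The published totals of the monitoring system's retrospective
#' evaluation: 136 melanoma patients, 5202 weekly questionnaires, 69 grade
#' >=2 immune-related adverse events. These are real study aggregates (not
#' patient-level data, which is unavailable), shipped as
#' `inst/extdata/reference_counts.json`.
#'
#' @return A named list of counts; see the JSON file for field meanings.
#' @examples
#' reference_cohort_counts()$n_questionnaires
#' @export
reference_cohort_counts <- function() {
  jsonlite::read_json(
    system.file("extdata", "reference_counts.json", package = "eprotriage"),
    simplifyVector = TRUE
  )
}

#' Confusion counts of the development cohort
#'
#' Assembles a [confusion_counts()] object from the packaged aggregate
#' counts, either over all grade >=2 IrAEs or restricted to symptomatic
#' ones (asymptomatic blood-test events removed from the event-level
#' cells).
#'
#' @param symptomatic_only Restrict TP/FN to symptomatic events.
#' @return A `confusion_counts`.
#' @examples
#' diagnostic_metrics(reference_confusion_counts())
#' @export
reference_confusion_counts <- function(symptomatic_only = FALSE) {
  k <- reference_cohort_counts()
  fn <- k$iraes_missed
  if (symptomatic_only) fn <- fn - k$iraes_blood_only_missed
  confusion_counts_from_totals(
    tp_irae = k$iraes_detected,
    fn_irae = fn,
    fp_quest = k$false_alert_questionnaires,
    green_quest = k$scores$green,
    prior_quest = k$scores$prior_irae_alert
  )
}
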