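# Cohort bundle: the full table set for one cohort, real or simulated.

#' Assemble a cohort bundle
#'
#' A bundle holds everything one cohort's evaluation needs: the patient
#' roster, the wide questionnaire table, the IrAE registry, the visit
#' schedules, and — for simulated cohorts — ground-truth annotations.
#' Construction enforces referential integrity (every questionnaire, IrAE
#' and visit must reference a known patient) and validates the
#' questionnaires against the item set.
#'
#' @param patients Tibble: `patient_id`, `sex`, `age_years`, `regimen`,
#'   `indication`, `cerebral_metastasis`, `enrolled_at`, `discontinued_at`,
#'   `discontinuation_reason`.
#' @param questionnaires Wide questionnaire tibble.
#' @param iraes IrAE registry tibble (see [link_detections()]).
#' @param visits Tibble: `patient_id`, `visit_date`.
#' @param ground_truth Optional tibble of simulator annotations:
#'   `questionnaire_id`, `gt_cause`, `gt_signature_irae`.
#' @param item_set Item table for questionnaire validation.
#' @return A list of class `cohort_bundle`.
#' @export
cohort_bundle <- function(patients, questionnaires, iraes, visits,
                          ground_truth = NULL,
                          item_set = standard_item_set()) {
  if (nrow(questionnaires) > 0) validate_questionnaires(questionnaires, item_set)
  for (tbl in list(
    list(questionnaires, "questionnaire"),
    list(iraes, "IrAE"), list(visits, "visit")
  )) {
    df <- tbl[[1]]
    if (nrow(df) == 0) next
    orphan <- setdiff(unique(df$patient_id), patients$patient_id)
    if (length(orphan) > 0) {
      abort(
        paste0(tbl[[2]], " references unknown patient: ", toString(head(orphan, 5))),
        class = "eprotriage_validation_error"
      )
    }
  }
  if (nrow(patients) > 0 && "discontinued_at" %in% names(patients)) {
    bad <- which(!is.na(patients$discontinued_at) &
      patients$discontinued_at < patients$enrolled_at)
    if (length(bad) > 0) {
      abort(paste0(
        "discontinued before enrollment: ",
        toString(patients$patient_id[bad])
      ), class = "eprotriage_validation_error")
    }
  }
  structure(
    list(
      patients = patients, questionnaires = questionnaires, iraes = iraes,
      visits = visits, ground_truth = ground_truth, item_set = item_set
    ),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat("  patients:      ", nrow(x$patients), "\n")
  cat("  questionnaires:", nrow(x$questionnaires), "\n")
  cat("  IrAEs:         ", nrow(x$iraes), "\n")
  cat("  visits:        ", nrow(x$visits), "\n")
  if (!is.null(x$ground_truth)) cat("  ground truth:   yes\n")
  invisible(x)
}
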