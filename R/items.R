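# Symptom item set and questionnaire validation.
#
# A questionnaire is one patient-week of self-reported symptom grades. In
# memory it is a row of a wide tibble: identifiers, a completion timestamp,
# one integer column per symptom item, plus free text and a callback flag.

#' Canonical symptom item identifiers
#'
#' The 11 items of the weekly toxicity questionnaire, in instrument order.
#' Fever follows the CTCAE v5 definition; the other ten are adapted from
#' PRO-CTCAE symptom items.
#'
#' @return Character vector of length 11.
#' @export
symptom_item_ids <- function() {
  c(
    "fever", "fatigue", "headache", "shortness_of_breath", "nausea_vomiting",
    "rash", "diarrhea", "decreased_appetite", "numbness_tingling",
    "general_pain", "blurred_vision"
  )
}

#' Standard 11-item symptom set
#'
#' Returns the canonical item table: one row per symptom with its display
#' label and per-item grade ceiling. Each response is graded from 0 (absent)
#' up to `max_grade`. All items run 0--3 except nausea/vomiting and
#' diarrhea, whose CTCAE analogues extend to grade 4 in outpatient
#' self-report; ceilings are configurable via [symptom_item_set()] because
#' the triage rule only distinguishes grade <=1 / =2 / >=3, so the ceiling
#' assignment cannot change any score.
#'
#' @return A tibble with columns `item_id`, `label`, `max_grade`.
#' @seealso [symptom_item_set()] for custom ceilings.
#' @examples
#' standard_item_set()
#' @export
standard_item_set <- function() {
  symptom_item_set()
}

#' Build a symptom item set with custom grade ceilings
#'
#' @param max_grades Named integer vector overriding per-item ceilings;
#'   names must be item ids, values 3 or 4.
#' @return A tibble with columns `item_id`, `label`, `max_grade`.
#' @export
symptom_item_set <- function(max_grades = NULL) {
  items <- tibble::tibble(
    item_id = symptom_item_ids(),
    label = c(
      "Fever", "Fatigue", "Headache", "Shortness of breath",
      "Nausea or vomiting", "Rash", "Diarrhea", "Decreased appetite",
      "Numbness or tingling", "General pain", "Blurred vision"
    ),
    max_grade = ifelse(
      symptom_item_ids() %in% c("nausea_vomiting", "diarrhea"), 4L, 3L
    )
  )
  if (!is.null(max_grades)) {
    bad <- setdiff(names(max_grades), items$item_id)
    if (length(bad) > 0) {
      abort(paste0("unknown item_id in max_grades: ", toString(bad)),
        class = "eprotriage_validation_error"
      )
    }
    if (!all(max_grades %in% c(3L, 4L))) {
      abort("max_grade must be 3 or 4", class = "eprotriage_validation_error")
    }
    idx <- match(names(max_grades), items$item_id)
    items$max_grade[idx] <- as.integer(max_grades)
  }
  items
}

#' Validate questionnaires against an item set
#'
#' Checks that every item of `item_set` is present exactly once per
#' questionnaire, that all grades are integers within `[0, max_grade]` of
#' their item, and that identifiers and timestamps are well formed. The
#' check is idempotent: a validated table passes again unchanged.
#'
#' @param questionnaires Wide tibble: `patient_id`, `questionnaire_id`,
#'   `completed_at` (POSIXct), one integer column per item, and optionally
#'   `free_text`, `callback_requested`.
#' @param item_set Item table as from [standard_item_set()].
#' @return `questionnaires`, invisibly, if valid; otherwise an error of
#'   class `eprotriage_validation_error` naming each offending
#'   questionnaire, item, and value.
#' @examples
#' q <- empty_questionnaire("P1", "Q1", as.POSIXct("2021-01-04 10:00", tz = "UTC"))
#' validate_questionnaires(q)
#' @export
validate_questionnaires <- function(questionnaires, item_set = standard_item_set()) {
  q <- questionnaires
  required <- c("patient_id", "questionnaire_id", "completed_at")
  missing_cols <- setdiff(required, names(q))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", toString(missing_cols)),
      class = "eprotriage_validation_error"
    )
  }
  missing_items <- setdiff(item_set$item_id, names(q))
  if (length(missing_items) > 0) {
    abort(paste0("missing item: ", toString(missing_items)),
      class = "eprotriage_validation_error"
    )
  }
  if (anyDuplicated(q$questionnaire_id) > 0) {
    dup <- unique(q$questionnaire_id[duplicated(q$questionnaire_id)])
    abort(paste0("duplicate questionnaire_id: ", toString(head(dup, 5))),
      class = "eprotriage_validation_error"
    )
  }
  problems <- character(0)
  for (i in seq_len(nrow(item_set))) {
    id <- item_set$item_id[i]
    ceiling_i <- item_set$max_grade[i]
    g <- q[[id]]
    bad <- which(is.na(g) | g %% 1 != 0 | g < 0 | g > ceiling_i)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "out-of-range grade: questionnaire %s item %s grade %s (max %d)",
        q$questionnaire_id[bad], id, as.character(g[bad]), ceiling_i
      ))
    }
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid questionnaire grades:", head(problems, 10)),
      collapse = "\n  "
    ), class = "eprotriage_validation_error")
  }
  invisible(questionnaires)
}

#' @rdname validate_questionnaires
#' @param questionnaire A one-row wide questionnaire tibble.
#' @export
validate_questionnaire <- function(questionnaire, item_set = standard_item_set()) {
  validate_questionnaires(questionnaire, item_set)
}

#' An all-zero questionnaire row
#'
#' Convenience constructor used in examples and tests: one questionnaire
#' with every symptom graded 0.
#'
#' @param patient_id,questionnaire_id Identifiers.
#' @param completed_at Completion timestamp (POSIXct, UTC recommended).
#' @param item_set Item table defining the grade columns.
#' @return A one-row wide questionnaire tibble.
#' @export
empty_questionnaire <- function(patient_id, questionnaire_id, completed_at,
                                item_set = standard_item_set()) {
  q <- tibble::tibble(
    patient_id = patient_id,
    questionnaire_id = questionnaire_id,
    completed_at = completed_at
  )
  for (id in item_set$item_id) q[[id]] <- 0L
  q$free_text <- NA_character_
  q$callback_requested <- FALSE
  q
}

#' Convert questionnaires between wide and long layouts
#'
#' The long layout has one row per (questionnaire, item) with columns
#' `patient_id`, `questionnaire_id`, `completed_at`, `item_id`, `grade`.
#' `questionnaires_from_long()` detects duplicate and unknown items, which
#' the wide layout cannot represent.
#'
#' @param questionnaires Wide questionnaire tibble.
#' @param long Long-format tibble.
#' @param item_set Item table.
#' @return The converted tibble.
#' @export
questionnaires_to_long <- function(questionnaires, item_set = standard_item_set()) {
  tidyr::pivot_longer(
    dplyr::select(
      questionnaires, "patient_id", "questionnaire_id", "completed_at",
      dplyr::all_of(item_set$item_id)
    ),
    cols = dplyr::all_of(item_set$item_id),
    names_to = "item_id", values_to = "grade"
  )
}

#' @rdname questionnaires_to_long
#' @export
questionnaires_from_long <- function(long, item_set = standard_item_set()) {
  unknown <- setdiff(unique(long$item_id), item_set$item_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown item_id: ", toString(unknown)),
      class = "eprotriage_validation_error"
    )
  }
  dup <- long |>
    dplyr::count(questionnaire_id, item_id) |>
    dplyr::filter(n > 1)
  if (nrow(dup) > 0) {
    abort(
      paste0(
        "duplicate item: questionnaire ", toString(head(dup$questionnaire_id, 5)),
        " item ", toString(head(dup$item_id, 5))
      ),
      class = "eprotriage_validation_error"
    )
  }
  wide <- tidyr::pivot_wider(long,
    id_cols = c("patient_id", "questionnaire_id", "completed_at"),
    names_from = "item_id", values_from = "grade"
  )
  missing_items <- setdiff(item_set$item_id, names(wide))
  if (length(missing_items) > 0 || anyNA(wide[item_set$item_id])) {
    miss <- missing_items
    if (length(miss) == 0) {
      miss <- item_set$item_id[colSums(is.na(wide[item_set$item_id])) > 0]
    }
    abort(paste0("missing item: ", toString(miss)),
      class = "eprotriage_validation_error"
    )
  }
  wide[c("patient_id", "questionnaire_id", "completed_at", item_set$item_id)]
}
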