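# Readers and writers for the cohort table set.
#
# On disk a bundle is a directory of CSVs (patients.csv, questionnaires.csv,
# iraes.csv, visits.csv, optionally ground_truth.csv) or a single nested
# JSON mirror. Dates are ISO-8601; questionnaires may be stored wide (one
# column per item) or long (one row per item), detected by the presence of
# an `item_id` column.

patient_cols <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    age_years = readr::col_integer(),
    regimen = readr::col_character(),
    indication = readr::col_character(),
    cerebral_metastasis = readr::col_logical(),
    enrolled_at = readr::col_date(),
    discontinued_at = readr::col_date(),
    discontinuation_reason = readr::col_character()
  )
}

irae_cols <- function() {
  readr::cols(
    irae_id = readr::col_character(),
    patient_id = readr::col_character(),
    category = readr::col_character(),
    ctcae_grade = readr::col_integer(),
    diagnosed_at = readr::col_date(),
    symptomatic = readr::col_logical(),
    related_items = readr::col_character(),
    managed_at = readr::col_date()
  )
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Emits `patients.csv`, `questionnaires.csv`, `iraes.csv`, `visits.csv`
#' and, when present, `ground_truth.csv`. Questionnaires are written wide
#' by default. All timestamps are ISO-8601 UTC; given identical input the
#' output bytes are identical, so seeded simulations round-trip
#' deterministically.
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Output directory (created if absent).
#' @param questionnaire_format `"wide"` (default) or `"long"`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, questionnaire_format = c("wide", "long")) {
  questionnaire_format <- match.arg(questionnaire_format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$patients, file.path(dir, "patients.csv"), na = "")
  q <- bundle$questionnaires
  if (questionnaire_format == "long") q <- questionnaires_to_long(q, bundle$item_set)
  readr::write_csv(q, file.path(dir, "questionnaires.csv"), na = "")
  readr::write_csv(bundle$iraes, file.path(dir, "iraes.csv"), na = "")
  readr::write_csv(bundle$visits, file.path(dir, "visits.csv"), na = "")
  if (!is.null(bundle$ground_truth)) {
    readr::write_csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"), na = "")
  }
  invisible(dir)
}

read_questionnaires_file <- function(path, item_set) {
  header <- names(readr::read_csv(path,
    n_max = 0, show_col_types = FALSE,
    progress = FALSE
  ))
  if ("item_id" %in% header) {
    long <- readr::read_csv(path,
      col_types = readr::cols(
        patient_id = readr::col_character(),
        questionnaire_id = readr::col_character(),
        completed_at = readr::col_datetime(),
        item_id = readr::col_character(),
        grade = readr::col_integer()
      ), progress = FALSE
    )
    questionnaires_from_long(long, item_set)
  } else {
    # build the spec from the header so optional columns don't warn
    per_col <- list(
      patient_id = readr::col_character(),
      questionnaire_id = readr::col_character(),
      completed_at = readr::col_datetime(),
      free_text = readr::col_character(),
      callback_requested = readr::col_logical()
    )
    spec <- do.call(readr::cols, c(
      per_col[intersect(names(per_col), header)],
      list(.default = readr::col_integer())
    ))
    readr::read_csv(path, col_types = spec, progress = FALSE)
  }
}

#' Read a cohort bundle from a directory of CSV files
#'
#' The inverse of [write_bundle()]: parses ISO-8601 dates, accepts wide or
#' long questionnaire layout, and re-validates the assembled bundle
#' (schema, grade ranges, referential integrity), so a corrupt file set
#' fails loudly with the offending identifiers.
#'
#' @param dir Directory holding the CSV table set.
#' @param item_set Item table for validation.
#' @return A [cohort_bundle()].
#' @export
read_bundle <- function(dir, item_set = standard_item_set()) {
  need <- c("patients.csv", "questionnaires.csv", "iraes.csv", "visits.csv")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f) > 0) {
    abort(paste0("missing bundle file(s) in ", dir, ": ", toString(missing_f)),
      class = "eprotriage_validation_error"
    )
  }
  patients <- readr::read_csv(file.path(dir, "patients.csv"),
    col_types = patient_cols(), progress = FALSE
  )
  questionnaires <- read_questionnaires_file(
    file.path(dir, "questionnaires.csv"), item_set
  )
  iraes <- readr::read_csv(file.path(dir, "iraes.csv"),
    col_types = irae_cols(), progress = FALSE
  )
  visits <- readr::read_csv(file.path(dir, "visits.csv"),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      visit_date = readr::col_date()
    ), progress = FALSE
  )
  gt_path <- file.path(dir, "ground_truth.csv")
  ground_truth <- NULL
  if (file.exists(gt_path)) {
    ground_truth <- readr::read_csv(gt_path,
      col_types = readr::cols(
        questionnaire_id = readr::col_character(),
        gt_cause = readr::col_character(),
        gt_signature_irae = readr::col_character()
      ), progress = FALSE
    )
  }
  cohort_bundle(patients, questionnaires, iraes, visits,
    ground_truth = ground_truth, item_set = item_set
  )
}

#' Write or read a cohort bundle as a single JSON document
#'
#' Lossless nested mirror of the CSV table set, convenient for archiving
#' one cohort as one file.
#'
#' @param bundle A [cohort_bundle()].
#' @param path JSON file path.
#' @param item_set Item table for validation on read.
#' @return `write_bundle_json()` returns `path` invisibly;
#'   `read_bundle_json()` a [cohort_bundle()].
#' @export
write_bundle_json <- function(bundle, path) {
  payload <- list(
    patients = bundle$patients,
    questionnaires = bundle$questionnaires,
    iraes = bundle$iraes,
    visits = bundle$visits
  )
  if (!is.null(bundle$ground_truth)) payload$ground_truth <- bundle$ground_truth
  jsonlite::write_json(payload, path,
    dataframe = "rows", na = "null",
    POSIXt = "ISO8601", Date = "ISO8601", digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_bundle_json
#' @export
read_bundle_json <- function(path, item_set = standard_item_set()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_date <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.Date(df[[cc]])
    df
  }
  patients <- fix_date(
    tibble::as_tibble(raw$patients),
    c("enrolled_at", "discontinued_at")
  )
  questionnaires <- tibble::as_tibble(raw$questionnaires)
  questionnaires$completed_at <- as.POSIXct(questionnaires$completed_at,
    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
  )
  for (id in intersect(item_set$item_id, names(questionnaires))) {
    questionnaires[[id]] <- as.integer(questionnaires[[id]])
  }
  iraes <- fix_date(
    tibble::as_tibble(raw$iraes),
    c("diagnosed_at", "managed_at")
  )
  visits <- fix_date(tibble::as_tibble(raw$visits), "visit_date")
  gt <- if (!is.null(raw$ground_truth)) tibble::as_tibble(raw$ground_truth) else NULL
  cohort_bundle(patients, questionnaires, iraes, visits,
    ground_truth = gt, item_set = item_set
  )
}
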