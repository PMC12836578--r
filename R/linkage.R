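# Alert-to-IrAE linkage: which grade >=2 immune-related adverse events were
# detected by a preceding alert questionnaire with related symptoms, and how
# each questionnaire is labeled for the confusion counts.

#' IrAE category identifiers
#'
#' @return Character vector of recognized adverse-event categories.
#' @export
irae_categories <- function() {
  c(
    "thyroiditis", "colitis_digestive", "hepatitis", "skin_toxicity",
    "hypophysitis", "hyperlipasemia", "rheumatological", "dry_syndrome",
    "myositis", "ophthalmological", "nephritis", "mixed_connective_tissue",
    "interstitial_pneumonitis", "other"
  )
}

#' Default category-to-item relatedness map
#'
#' Which questionnaire items count as "related symptoms" for each IrAE
#' category when no per-event `related_items` annotation is available. The
#' map ships as a YAML configuration file
#' (`system.file("extdata", "relatedness_default.yaml", package = "eprotriage")`)
#' so sites can adapt it without touching code.
#'
#' @param path Optional path to an alternative YAML map.
#' @return Named list: category -> character vector of item ids.
#' @export
default_relatedness <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "relatedness_default.yaml",
      package = "eprotriage"
    )
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) as.character(unlist(x)))
}

#' Miss-reason categories for undetected IrAEs
#' @return Character vector of the four reasons, in assignment priority order.
#' @export
miss_reasons <- function() {
  c(
    "blood_disorder_no_clinical_impact", "questionnaire_not_completed",
    "symptoms_not_in_questionnaire", "symptoms_not_reported"
  )
}

split_items <- function(x) {
  if (!nzchar(x) || identical(x, "none")) {
    character(0)
  } else {
    strsplit(x, ";", fixed = TRUE)[[1]]
  }
}

# per-event related-item sets: NA means "use the category map", "none" (or
# an empty string) means "explicitly none" (e.g. an asymptomatic lab
# finding). The "none" token survives CSV round trips, where an empty
# string would collapse to NA.
irae_related <- function(iraes, relatedness) {
  lapply(seq_len(nrow(iraes)), function(i) {
    own <- if ("related_items" %in% names(iraes)) iraes$related_items[i] else NA_character_
    if (is.na(own)) {
      relatedness[[iraes$category[i]]] %||% character(0)
    } else {
      split_items(own)
    }
  })
}

#' Link alerts to grade >=2 IrAEs and label every questionnaire
#'
#' An IrAE counts as correctly detected if some alert (orange/red)
#' questionnaire of the same patient (a) was completed on or before the
#' diagnosis date, (b) no more than `window_days` before it, and (c)
#' reports at least one moderate or severe symptom in the event's related
#' item set. Among qualifying alerts only the earliest one is the
#' detector, so an event is never counted twice; later qualifying alerts —
#' and alerts whose related symptoms recur within `window_days` after the
#' diagnosis — are labeled `alert_prior_irae`. Alerts qualifying for no
#' event are `alert_false`; green questionnaires are `green`.
#'
#' Undetected events are assigned a miss reason, in priority order:
#' asymptomatic blood disorder; no questionnaire completed in the window
#' before diagnosis; related symptoms not part of the instrument; symptoms
#' present in the instrument but not reported.
#'
#' @param questionnaires Wide questionnaire tibble.
#' @param iraes IrAE registry tibble: `irae_id`, `patient_id`, `category`,
#'   `ctcae_grade`, `diagnosed_at` (Date), `symptomatic` (logical), and
#'   optionally `related_items` (semicolon-joined item ids overriding the
#'   map; `NA` = use the map, `"none"` = explicitly no related symptoms)
#'   and `managed_at`. Only grade >=2 rows are consumed.
#' @param policy A [scoring_policy()].
#' @param window_days Maximum days from alert to diagnosis, default 30.
#' @param relatedness Category-to-items map, default [default_relatedness()].
#' @return A list with class `detection_linkage`:
#'   * `links`: one row per grade >=2 IrAE — `irae_id`, `patient_id`,
#'     `category`, `ctcae_grade`, `symptomatic`, `diagnosed_at`,
#'     `detecting_questionnaire` (NA if missed), `lead_days`, `miss_reason`.
#'   * `labels`: one row per questionnaire — `questionnaire_id`, `color`,
#'     `label`, `followed_by_irae` (a grade >=2 event of the same patient
#'     diagnosed within `window_days` after the questionnaire).
#' @export
link_detections <- function(questionnaires, iraes, policy = scoring_policy(),
                            window_days = 30,
                            relatedness = default_relatedness()) {
  scores <- score_questionnaires(questionnaires, policy)
  # an IrAE patient with no questionnaire is allowed (they may simply never
  # have completed one); an unknown category is not
  bad_cat <- setdiff(unique(iraes$category), irae_categories())
  if (length(bad_cat) > 0) {
    abort(paste0("unknown IrAE category: ", toString(bad_cat)),
      class = "eprotriage_validation_error"
    )
  }
  ev <- dplyr::arrange(
    dplyr::filter(iraes, ctcae_grade >= 2),
    diagnosed_at, irae_id
  )
  related <- irae_related(ev, relatedness)
  instrument <- policy$item_set$item_id

  # per-questionnaire set of moderate/severe items
  q_items <- vector("list", nrow(questionnaires))
  is_alert <- scores$color != "green"
  for (id in instrument) {
    b <- bucket_grade(questionnaires[[id]], id, policy)
    hit <- which(b != "absent_slight")
    for (i in hit) q_items[[i]] <- c(q_items[[i]], id)
  }
  q_date <- as.Date(scores$completed_at, tz = attr(scores$completed_at, "tzone") %||% "UTC")

  n_ev <- nrow(ev)
  detecting <- rep(NA_character_, n_ev)
  lead <- rep(NA_integer_, n_ev)
  reason <- rep(NA_character_, n_ev)
  q_label <- ifelse(is_alert, "alert_false", "green")
  followed <- rep(FALSE, nrow(scores))
  by_patient <- split(seq_len(nrow(scores)), scores$patient_id)

  for (i in seq_len(n_ev)) {
    d <- ev$diagnosed_at[i]
    rel <- related[[i]]
    cand <- by_patient[[ev$patient_id[i]]]
    delta <- as.integer(d - q_date[cand])
    pre <- cand[delta >= 0 & delta <= window_days]
    followed[pre] <- TRUE
    rel_in <- intersect(rel, instrument)
    has_rel <- function(ix) {
      ix[vapply(
        q_items[ix], function(s) length(intersect(s, rel_in)) > 0, logical(1)
      )]
    }
    qualifies <- has_rel(pre[is_alert[pre]])
    if (length(qualifies) > 0) {
      ord <- qualifies[order(q_date[qualifies], scores$questionnaire_id[qualifies])]
      first <- ord[1]
      detecting[i] <- scores$questionnaire_id[first]
      lead[i] <- as.integer(d - q_date[first])
      q_label[first] <- "alert_detecting"
      later <- setdiff(ord, first)
      q_label[later][q_label[later] != "alert_detecting"] <- "alert_prior_irae"
    } else {
      reason[i] <- if (!ev$symptomatic[i]) {
        "blood_disorder_no_clinical_impact"
      } else if (length(pre) == 0) {
        "questionnaire_not_completed"
      } else if (length(rel_in) == 0) {
        "symptoms_not_in_questionnaire"
      } else {
        "symptoms_not_reported"
      }
    }
    # alerts echoing the event's symptoms shortly after diagnosis relate to
    # an already-known IrAE, not a new one
    post_cand <- cand[delta < 0 & delta >= -window_days]
    post <- has_rel(post_cand[is_alert[post_cand]])
    q_label[post][q_label[post] == "alert_false"] <- "alert_prior_irae"
  }

  links <- tibble::tibble(
    irae_id = ev$irae_id,
    patient_id = ev$patient_id,
    category = ev$category,
    ctcae_grade = ev$ctcae_grade,
    symptomatic = ev$symptomatic,
    diagnosed_at = ev$diagnosed_at,
    detecting_questionnaire = detecting,
    lead_days = lead,
    miss_reason = reason
  )
  labels <- tibble::tibble(
    questionnaire_id = scores$questionnaire_id,
    color = scores$color,
    label = q_label,
    followed_by_irae = followed
  )
  structure(list(links = links, labels = labels, window_days = window_days),
    class = "detection_linkage"
  )
}

#' @export
print.detection_linkage <- function(x, ...) {
  cat("<detection_linkage>\n")
  cat(
    "  IrAEs (grade >=2):", nrow(x$links), "- detected:",
    sum(!is.na(x$links$detecting_questionnaire)), "\n"
  )
  cat("  questionnaires:", nrow(x$labels), "\n")
  print(table(x$labels$label))
  invisible(x)
}

#' Days saved relative to the next scheduled visit
#'
#' For an alert-detected event, the days saved is the gap between the IrAE
#' diagnosis (when management actually started) and the next scheduled
#' clinic visit after the detecting questionnaire — the earliest moment the
#' event would otherwise have surfaced. Floored at zero; `NA` when the
#' schedule holds no later visit.
#'
#' @param detected_on Date(s) of the detecting questionnaire.
#' @param diagnosed_on Date(s) of IrAE diagnosis.
#' @param visit_dates Ordered Date vector of scheduled visits (one
#'   patient's schedule; call per patient).
#' @return Integer days saved, `NA` where undefined.
#' @examples
#' time_saved(as.Date("2021-03-01"), as.Date("2021-03-04"),
#'   visit_dates = as.Date(c("2021-02-15", "2021-03-08"))
#' )
#' @export
time_saved <- function(detected_on, diagnosed_on, visit_dates) {
  vapply(seq_along(detected_on), function(i) {
    nxt <- visit_dates[visit_dates > detected_on[i]]
    if (length(nxt) == 0) {
      return(NA_integer_)
    }
    max(0L, as.integer(min(nxt) - diagnosed_on[i]))
  }, integer(1))
}

#' Attach days-saved to detection links
#'
#' @param linkage A `detection_linkage` from [link_detections()].
#' @param questionnaires Wide questionnaire tibble (for detection dates).
#' @param visits Visit schedule tibble: `patient_id`, `visit_date` (Date).
#' @return The `links` tibble with a `days_saved` column.
#' @export
add_time_saved <- function(linkage, questionnaires, visits) {
  links <- linkage$links
  q_date <- setNames(
    as.Date(questionnaires$completed_at,
      tz = attr(questionnaires$completed_at, "tzone") %||% "UTC"
    ),
    questionnaires$questionnaire_id
  )
  links$days_saved <- NA_integer_
  det <- which(!is.na(links$detecting_questionnaire))
  for (i in det) {
    vd <- sort(visits$visit_date[visits$patient_id == links$patient_id[i]])
    links$days_saved[i] <- time_saved(
      q_date[[links$detecting_questionnaire[i]]],
      links$diagnosed_at[i], vd
    )
  }
  links
}
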