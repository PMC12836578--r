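# Fixture builders and independent brute-force oracles shared across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# one wide questionnaire with chosen grades, everything else 0
make_q <- function(patient_id, questionnaire_id, completed_at, ...) {
  q <- empty_questionnaire(patient_id, questionnaire_id, utc(completed_at))
  grades <- list(...)
  for (id in names(grades)) q[[id]] <- as.integer(grades[[id]])
  q
}

make_irae <- function(irae_id, patient_id, category, ctcae_grade, diagnosed_at,
                      symptomatic = TRUE, related_items = NA_character_) {
  tibble::tibble(
    irae_id = irae_id, patient_id = patient_id, category = category,
    ctcae_grade = as.integer(ctcae_grade),
    diagnosed_at = as.Date(diagnosed_at), symptomatic = symptomatic,
    related_items = related_items, managed_at = as.Date(diagnosed_at)
  )
}

make_patient <- function(patient_id, enrolled_at, discontinued_at = NA) {
  tibble::tibble(
    patient_id = patient_id, sex = "female", age_years = 57L,
    regimen = "anti_pd1_mono", indication = "adjuvant",
    cerebral_metastasis = FALSE, enrolled_at = as.Date(enrolled_at),
    discontinued_at = as.Date(discontinued_at),
    discontinuation_reason = NA_character_
  )
}

# random wide questionnaires, grades weighted toward 0 so all colors occur
random_questionnaires <- function(n, item_set = standard_item_set(),
                                  patient_id = "P1") {
  q <- tibble::tibble(
    patient_id = patient_id,
    questionnaire_id = sprintf("Q%05d", seq_len(n)),
    completed_at = utc("2021-01-04 10:00") + (seq_len(n) - 1) * 3600
  )
  for (i in seq_len(nrow(item_set))) {
    ceiling_i <- item_set$max_grade[i]
    g <- sample(0:4, n, TRUE, prob = c(0.55, 0.2, 0.15, 0.07, 0.03))
    q[[item_set$item_id[i]]] <- as.integer(pmin(g, ceiling_i))
  }
  q
}

# --- independent scoring oracle: plain loops and if-chains ----------------
oracle_score_row <- function(qrow, policy = scoring_policy()) {
  m <- 0L
  s <- 0L
  ov <- policy$escalation_overrides
  for (i in seq_len(nrow(policy$item_set))) {
    id <- policy$item_set$item_id[i]
    g <- qrow[[id]]
    severe <- g >= 3
    if (!severe && length(ov) > 0 && id %in% names(ov) && g >= ov[[id]]) {
      severe <- TRUE
    }
    if (severe) {
      s <- s + 1L
    } else if (g == 2) {
      m <- m + 1L
    }
  }
  color <- if (s >= 1L) {
    "red"
  } else if (m >= 3L) {
    "red"
  } else if (m >= 1L) {
    "orange"
  } else {
    "green"
  }
  list(color = color, n_moderate = m, n_severe = s)
}

# items reported moderate/severe on one questionnaire, per the oracle
oracle_ms_items <- function(qrow, policy = scoring_policy()) {
  out <- character(0)
  ov <- policy$escalation_overrides
  for (id in policy$item_set$item_id) {
    g <- qrow[[id]]
    hit <- g >= 2
    if (!hit && length(ov) > 0 && id %in% names(ov) && g >= ov[[id]]) hit <- TRUE
    if (hit) out <- c(out, id)
  }
  out
}

# --- independent linkage oracle: exhaustive (questionnaire, IrAE) scan ----
oracle_link <- function(questionnaires, iraes, policy = scoring_policy(),
                        window_days = 30,
                        relatedness = default_relatedness()) {
  ev <- iraes[iraes$ctcae_grade >= 2, ]
  ev <- ev[order(ev$diagnosed_at, ev$irae_id), ]
  nq <- nrow(questionnaires)
  q_date <- as.Date(questionnaires$completed_at, tz = "UTC")
  q_alert <- logical(nq)
  q_ms <- vector("list", nq)
  for (j in seq_len(nq)) {
    sc <- oracle_score_row(questionnaires[j, ], policy)
    q_alert[j] <- sc$color != "green"
    q_ms[[j]] <- oracle_ms_items(questionnaires[j, ], policy)
  }
  label <- ifelse(q_alert, "alert_false", "green")
  detecting <- character(nrow(ev))
  lead <- rep(NA_integer_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    rel <- if (is.na(ev$related_items[i])) {
      relatedness[[ev$category[i]]]
    } else if (nzchar(ev$related_items[i]) && ev$related_items[i] != "none") {
      strsplit(ev$related_items[i], ";")[[1]]
    } else {
      character(0)
    }
    rel <- intersect(rel, policy$item_set$item_id)
    qual <- integer(0)
    post <- integer(0)
    for (j in seq_len(nq)) {
      if (questionnaires$patient_id[j] != ev$patient_id[i] || !q_alert[j]) next
      d <- as.integer(ev$diagnosed_at[i] - q_date[j])
      if (length(intersect(q_ms[[j]], rel)) == 0) next
      if (d >= 0 && d <= window_days) qual <- c(qual, j)
      if (d < 0 && d >= -window_days) post <- c(post, j)
    }
    if (length(qual) > 0) {
      ordq <- qual[order(q_date[qual], questionnaires$questionnaire_id[qual])]
      first <- ordq[1]
      detecting[i] <- questionnaires$questionnaire_id[first]
      lead[i] <- as.integer(ev$diagnosed_at[i] - q_date[first])
      label[first] <- "alert_detecting"
      for (j in setdiff(ordq, first)) {
        if (label[j] != "alert_detecting") label[j] <- "alert_prior_irae"
      }
    } else {
      detecting[i] <- NA_character_
    }
    for (j in post) if (label[j] == "alert_false") label[j] <- "alert_prior_irae"
  }
  list(
    detecting = stats::setNames(detecting, ev$irae_id),
    lead = stats::setNames(lead, ev$irae_id),
    label = stats::setNames(label, questionnaires$questionnaire_id)
  )
}

# small random cohort for linkage property tests
random_linkage_cohort <- function(n_q, n_irae, n_patients = 3) {
  pids <- sprintf("P%d", seq_len(n_patients))
  q <- random_questionnaires(n_q,
    patient_id = sample(pids, n_q, TRUE)
  )
  q$completed_at <- utc("2021-02-01 10:00") + sample(0:80, n_q, TRUE) * 86400
  cats <- irae_categories()
  iraes <- tibble::tibble(
    irae_id = sprintf("E%03d", seq_len(n_irae)),
    patient_id = sample(pids, n_irae, TRUE),
    category = sample(cats, n_irae, TRUE),
    ctcae_grade = sample(1:4, n_irae, TRUE),
    diagnosed_at = as.Date("2021-02-01") + sample(0:90, n_irae, TRUE),
    symptomatic = sample(c(TRUE, FALSE), n_irae, TRUE, prob = c(0.7, 0.3)),
    related_items = NA_character_,
    managed_at = as.Date(NA)
  )
  iraes$related_items[iraes$symptomatic == FALSE] <- "none"
  list(questionnaires = q, iraes = iraes)
}
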