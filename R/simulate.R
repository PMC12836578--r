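# Seeded synthetic-cohort simulator.
#
# Generates patients, weekly questionnaires, an IrAE registry, visit
# schedules and ground-truth annotations with the statistical structure of
# the development cohort, so scoring and evaluation are testable end-to-end
# without patient data. Every random draw flows from params$seed, so a
# given seed yields a byte-identical bundle.

#' Simulation parameters
#'
#' Defaults emulate the development cohort: median follow-up 46 weeks
#' (truncated log-normal over 1--227), weekly completion probability 0.89,
#' 9.6% combination-regimen patients, a grade >=2 IrAE in 36.8% of
#' patients of which 44.9% are asymptomatic blood-test findings, 24.6%
#' grade 3/4 events, a 14.6% per-questionnaire false-alert rate split over
#' the six annotated cause categories, and six-week visit intervals.
#' `symptom_signature_strength` is the probability that a symptomatic IrAE
#' lifts its related items to grade >=2 on the questionnaire of the week
#' preceding diagnosis; its default 0.80 makes the expected symptomatic
#' detection rate `strength * adherence ~= 0.71` and the overall rate
#' `(1 - blood_only_frac) * strength * adherence ~= 0.39`, the cohort's
#' observed detection performance.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; every draw of [simulate_cohort()] flows from it.
#' @param followup_weeks_median,followup_weeks_sdlog,followup_weeks_range
#'   Log-normal follow-up length in weeks, truncated to the range.
#' @param adherence_prob Weekly questionnaire completion probability.
#' @param combo_frac Fraction on ipilimumab+nivolumab (rest anti-PD-1 mono).
#' @param metastatic_frac Fraction treated for metastatic disease.
#' @param irae_patient_prob Probability a patient has at least one grade
#'   >=2 IrAE.
#' @param extra_irae_lambda Poisson mean of additional IrAEs beyond the
#'   first for affected patients.
#' @param blood_only_frac Fraction of IrAEs that are asymptomatic
#'   blood-test findings.
#' @param grade34_frac Fraction of IrAEs of grade 3/4 (anti-PD-1 mono).
#' @param grade34_combo_multiplier Multiplier on `grade34_frac` for
#'   combination-regimen patients (capped at 0.95).
#' @param category_weights Named category sampling weights (sum 1).
#' @param symptom_signature_strength See above.
#' @param false_alert_rate Per-questionnaire probability of a non-IrAE alert.
#' @param red_false_frac Fraction of injected false alerts that are red.
#' @param cause_mix Named six-category mixture for false-alert causes (sum 1).
#' @param alert_symptom_weights Named per-item weights used to pick which
#'   symptoms an injected false alert elevates (fatigue/general-pain heavy).
#' @param baseline_grade1_prob Probability an item is grade 1 rather than 0
#'   on an ordinary week (background noise; never alerts by itself).
#' @param visit_interval_days Days between scheduled clinic visits.
#' @param start_date,enrollment_span_days Enrollment dates are uniform over
#'   `[start_date, start_date + enrollment_span_days)`.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 136,
                              seed = 1L,
                              followup_weeks_median = 46,
                              followup_weeks_sdlog = 0.8,
                              followup_weeks_range = c(1, 227),
                              adherence_prob = 0.89,
                              combo_frac = 0.096,
                              metastatic_frac = 0.338,
                              irae_patient_prob = 0.368,
                              extra_irae_lambda = 0.38,
                              blood_only_frac = 0.449,
                              grade34_frac = 0.246,
                              grade34_combo_multiplier = 3,
                              category_weights = NULL,
                              symptom_signature_strength = 0.8,
                              false_alert_rate = 0.146,
                              red_false_frac = 0.158,
                              cause_mix = NULL,
                              alert_symptom_weights = NULL,
                              baseline_grade1_prob = 0.08,
                              visit_interval_days = 42,
                              start_date = as.Date("2020-01-06"),
                              enrollment_span_days = 365) {
  if (is.null(category_weights)) {
    # event counts of the development cohort's registry, normalized
    counts <- c(
      thyroiditis = 19, colitis_digestive = 9, hepatitis = 8,
      skin_toxicity = 8, hypophysitis = 6, hyperlipasemia = 5,
      rheumatological = 4, dry_syndrome = 3, myositis = 2,
      ophthalmological = 2, nephritis = 1, mixed_connective_tissue = 1,
      interstitial_pneumonitis = 1
    )
    category_weights <- counts / sum(counts)
  }
  if (is.null(cause_mix)) {
    counts <- c(
      functional_nonspecific = 246, previous_condition = 142,
      independent_condition = 140, input_error = 111,
      overestimated_grade1 = 63, tumor_burden = 59
    )
    cause_mix <- counts / sum(counts)
  }
  if (is.null(alert_symptom_weights)) {
    # symptom shares observed across alert questionnaires, renormalized
    alert_symptom_weights <- c(
      fatigue = 0.30, general_pain = 0.20, shortness_of_breath = 0.11,
      rash = 0.10, decreased_appetite = 0.07, numbness_tingling = 0.055,
      headache = 0.05, nausea_vomiting = 0.045, diarrhea = 0.04,
      blurred_vision = 0.035, fever = 0.035
    )
    alert_symptom_weights <- alert_symptom_weights / sum(alert_symptom_weights)
  }
  params <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    followup_weeks_median = followup_weeks_median,
    followup_weeks_sdlog = followup_weeks_sdlog,
    followup_weeks_range = followup_weeks_range,
    adherence_prob = adherence_prob, combo_frac = combo_frac,
    metastatic_frac = metastatic_frac,
    irae_patient_prob = irae_patient_prob,
    extra_irae_lambda = extra_irae_lambda,
    blood_only_frac = blood_only_frac, grade34_frac = grade34_frac,
    grade34_combo_multiplier = grade34_combo_multiplier,
    category_weights = category_weights,
    symptom_signature_strength = symptom_signature_strength,
    false_alert_rate = false_alert_rate, red_false_frac = red_false_frac,
    cause_mix = cause_mix, alert_symptom_weights = alert_symptom_weights,
    baseline_grade1_prob = baseline_grade1_prob,
    visit_interval_days = visit_interval_days,
    start_date = start_date, enrollment_span_days = enrollment_span_days
  )
  validate_simulation_params(params)
  structure(params, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  probs <- c(
    adherence_prob = p$adherence_prob, combo_frac = p$combo_frac,
    metastatic_frac = p$metastatic_frac,
    irae_patient_prob = p$irae_patient_prob,
    blood_only_frac = p$blood_only_frac, grade34_frac = p$grade34_frac,
    symptom_signature_strength = p$symptom_signature_strength,
    false_alert_rate = p$false_alert_rate, red_false_frac = p$red_false_frac,
    baseline_grade1_prob = p$baseline_grade1_prob
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(paste0("probabilities outside [0, 1]: ", toString(bad)),
      class = "eprotriage_validation_error"
    )
  }
  for (mx in c("category_weights", "cause_mix", "alert_symptom_weights")) {
    if (abs(sum(p[[mx]]) - 1) > 1e-9 || any(p[[mx]] < 0)) {
      abort(paste0(mx, " must be non-negative and sum to 1 (tolerance 1e-9)"),
        class = "eprotriage_validation_error"
      )
    }
  }
  if (p$n_patients < 0) abort("n_patients must be >= 0")
  unknown <- setdiff(names(p$cause_mix), false_alert_causes())
  if (length(unknown) > 0) {
    abort(paste0("unknown false-alert cause: ", toString(unknown)),
      class = "eprotriage_validation_error"
    )
  }
  unknown <- setdiff(names(p$category_weights), irae_categories())
  if (length(unknown) > 0) {
    abort(paste0("unknown IrAE category: ", toString(unknown)),
      class = "eprotriage_validation_error"
    )
  }
  invisible(p)
}

#' Read simulation parameters from a YAML file
#'
#' Scalar fields override the defaults of [simulation_params()]; named
#' mappings (`category_weights`, `cause_mix`, `alert_symptom_weights`)
#' replace them wholesale.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's value.
#' @return A `simulation_params`.
#' @export
read_simulation_params <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  for (mx in c("category_weights", "cause_mix", "alert_symptom_weights")) {
    if (!is.null(raw[[mx]])) raw[[mx]] <- unlist(raw[[mx]])
  }
  if (!is.null(raw$start_date)) raw$start_date <- as.Date(raw$start_date)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(simulation_params, raw)
}

#' Simulate a synthetic cohort
#'
#' Draws patients, weekly questionnaires, IrAE events, visit schedules and
#' ground-truth annotations under `params`. The generative model:
#'
#' 1. Each patient gets an enrollment date, a truncated log-normal
#'    follow-up, and a weekly questionnaire grid anchored at enrollment;
#'    each week's questionnaire is completed with the adherence
#'    probability, at a uniform time of day.
#' 2. Ordinary weeks carry background noise only (items at grade 0/1),
#'    which never alerts.
#' 3. IrAE events are placed uniformly over follow-up (at least two weeks
#'    in). A symptomatic event leaves, with probability
#'    `symptom_signature_strength`, a symptom signature on the last
#'    completed questionnaire before diagnosis: its related items rise to
#'    grade 2 (one item to grade 3 for a grade 3/4 event). Asymptomatic
#'    blood-test events leave no signature. Symptomatic events always draw
#'    a category whose related items exist in the instrument.
#' 4. Signature-free questionnaires become false alerts with probability
#'    `false_alert_rate`: one to three items are elevated (red with
#'    probability `red_false_frac`) and the generating cause is drawn from
#'    `cause_mix` and recorded as ground truth.
#'
#' @param params A [simulation_params()].
#' @return A [cohort_bundle()] whose `iraes` carry a `gt_detectable`
#'   column and whose `ground_truth` table maps each questionnaire to its
#'   generating cause (`gt_cause`) and/or signature event
#'   (`gt_signature_irae`).
#' @examples
#' b <- simulate_cohort(simulation_params(n_patients = 20, seed = 42))
#' b
#' @export
simulate_cohort <- function(params) {
  validate_simulation_params(params)
  p <- params
  set.seed(p$seed)
  items <- standard_item_set()
  relatedness <- default_relatedness()
  nonempty_cats <- names(Filter(function(x) length(x) > 0, relatedness))

  if (p$n_patients == 0) {
    return(empty_bundle(items))
  }

  # --- patients -----------------------------------------------------------
  pid <- sprintf("P%04d", seq_len(p$n_patients))
  sex <- sample(c("male", "female"), p$n_patients, TRUE, c(0.559, 0.441))
  age <- pmin(85L, pmax(23L, as.integer(round(rnorm(p$n_patients, 57.5, 13)))))
  regimen <- ifelse(runif(p$n_patients) < p$combo_frac,
    "combo_ipi_nivo", "anti_pd1_mono"
  )
  indication <- ifelse(runif(p$n_patients) < p$metastatic_frac,
    "metastatic", "adjuvant"
  )
  cerebral <- runif(p$n_patients) < 0.12
  enrolled <- p$start_date + floor(runif(p$n_patients, 0, p$enrollment_span_days))
  fu_weeks <- round(rlnorm(
    p$n_patients, log(p$followup_weeks_median), p$followup_weeks_sdlog
  ))
  fu_weeks <- pmin(p$followup_weeks_range[2], pmax(p$followup_weeks_range[1], fu_weeks))
  discontinued <- enrolled + fu_weeks * 7
  reason <- sample(
    c("scheduled_end", "progression", "transfer", "death", "refusal"),
    p$n_patients, TRUE, c(0.49, 0.423, 0.029, 0.029, 0.029)
  )
  patients <- tibble::tibble(
    patient_id = pid, sex = sex, age_years = age, regimen = regimen,
    indication = indication, cerebral_metastasis = cerebral,
    enrolled_at = enrolled, discontinued_at = discontinued,
    discontinuation_reason = reason
  )

  # --- visit schedules ----------------------------------------------------
  visits <- purrr::map_dfr(seq_len(p$n_patients), function(i) {
    vd <- if (enrolled[i] + p$visit_interval_days > discontinued[i]) {
      as.Date(character(0))
    } else {
      seq(enrolled[i] + p$visit_interval_days, discontinued[i],
        by = p$visit_interval_days
      )
    }
    if (length(vd) == 0) {
      return(tibble::tibble(patient_id = character(0), visit_date = as.Date(character(0))))
    }
    tibble::tibble(patient_id = pid[i], visit_date = vd)
  })

  # --- questionnaire grid -------------------------------------------------
  idx <- rep(seq_len(p$n_patients), fu_weeks)
  week <- unlist(lapply(fu_weeks, function(w) seq_len(w) - 1L))
  completed <- runif(length(idx)) < p$adherence_prob
  idx <- idx[completed]
  week <- week[completed]
  n_q <- length(idx)
  q_day <- enrolled[idx] + week * 7L
  q_time <- as.POSIXct(as.character(q_day), tz = "UTC") + runif(n_q, 8, 21) * 3600
  qid <- sprintf("%s-W%03d", pid[idx], week)

  grades <- matrix(0L, nrow = n_q, ncol = nrow(items),
    dimnames = list(NULL, items$item_id)
  )
  noise <- matrix(runif(n_q * nrow(items)) < p$baseline_grade1_prob, nrow = n_q)
  grades[noise] <- 1L

  gt_signature <- rep(NA_character_, n_q)
  gt_cause <- rep(NA_character_, n_q)

  # --- IrAE events + symptom signatures -----------------------------------
  has_irae <- runif(p$n_patients) < p$irae_patient_prob
  irae_rows <- list()
  k <- 0
  for (i in seq_len(p$n_patients)) {
    if (!has_irae[i] || fu_weeks[i] < 3) next
    n_ev <- 1L + rpois(1, p$extra_irae_lambda)
    for (e in seq_len(n_ev)) {
      k <- k + 1
      d <- enrolled[i] + floor(runif(1, 14, fu_weeks[i] * 7 + 1))
      symptomatic <- runif(1) >= p$blood_only_frac
      cat_pool <- if (symptomatic) {
        w <- p$category_weights[names(p$category_weights) %in% nonempty_cats]
        w / sum(w)
      } else {
        p$category_weights
      }
      category <- sample(names(cat_pool), 1, prob = cat_pool)
      p34 <- min(0.95, p$grade34_frac *
        if (regimen[i] == "combo_ipi_nivo") p$grade34_combo_multiplier else 1)
      grade <- if (runif(1) < p34) sample(3:4, 1, prob = c(0.7, 0.3)) else 2L
      detectable <- FALSE
      if (symptomatic && runif(1) < p$symptom_signature_strength) {
        wk <- as.integer(floor((d - enrolled[i]) / 7))
        row <- which(idx == i & week == wk)
        if (length(row) == 1) {
          rel <- intersect(relatedness[[category]], items$item_id)
          grades[row, rel] <- pmax(grades[row, rel], 2L)
          if (grade >= 3) grades[row, rel[1]] <- 3L
          irae_id_k <- sprintf("E%04d", k)
          gt_signature[row] <- ifelse(is.na(gt_signature[row]), irae_id_k,
            paste(gt_signature[row], irae_id_k, sep = ";")
          )
          detectable <- TRUE
        }
      }
      irae_rows[[k]] <- tibble::tibble(
        irae_id = sprintf("E%04d", k), patient_id = pid[i],
        category = category, ctcae_grade = as.integer(grade),
        diagnosed_at = d, symptomatic = symptomatic,
        # a blood-test finding has no reportable symptoms: explicitly none
        related_items = if (symptomatic) NA_character_ else "none",
        managed_at = d, gt_detectable = detectable
      )
    }
  }
  iraes <- if (k > 0) dplyr::bind_rows(irae_rows) else empty_iraes()

  # --- injected false alerts ----------------------------------------------
  eligible <- which(is.na(gt_signature))
  is_false <- eligible[runif(length(eligible)) < p$false_alert_rate]
  for (row in is_false) {
    gt_cause[row] <- sample(names(p$cause_mix), 1, prob = p$cause_mix)
    if (runif(1) < p$red_false_frac) {
      it <- sample(names(p$alert_symptom_weights), 1,
        prob = p$alert_symptom_weights
      )
      grades[row, it] <- 3L
    } else {
      n_it <- sample(1:2, 1, prob = c(0.7, 0.3))
      it <- sample(names(p$alert_symptom_weights), n_it,
        prob = p$alert_symptom_weights
      )
      grades[row, it] <- 2L
    }
  }

  questionnaires <- tibble::tibble(
    patient_id = pid[idx], questionnaire_id = qid, completed_at = q_time
  )
  for (id in items$item_id) questionnaires[[id]] <- grades[, id]
  questionnaires$free_text <- NA_character_
  questionnaires$callback_requested <- FALSE
  ord <- order(questionnaires$patient_id, questionnaires$completed_at)
  questionnaires <- questionnaires[ord, ]
  ground_truth <- tibble::tibble(
    questionnaire_id = qid, gt_cause = gt_cause,
    gt_signature_irae = gt_signature
  )[ord, ]

  cohort_bundle(patients, questionnaires, iraes, visits,
    ground_truth = ground_truth, item_set = items
  )
}

empty_iraes <- function() {
  tibble::tibble(
    irae_id = character(0), patient_id = character(0), category = character(0),
    ctcae_grade = integer(0), diagnosed_at = as.Date(character(0)),
    symptomatic = logical(0), related_items = character(0),
    managed_at = as.Date(character(0)), gt_detectable = logical(0)
  )
}

empty_bundle <- function(item_set = standard_item_set()) {
  q <- tibble::tibble(
    patient_id = character(0), questionnaire_id = character(0),
    completed_at = as.POSIXct(character(0), tz = "UTC")
  )
  for (id in item_set$item_id) q[[id]] <- integer(0)
  q$free_text <- character(0)
  q$callback_requested <- logical(0)
  cohort_bundle(
    patients = tibble::tibble(
      patient_id = character(0), sex = character(0), age_years = integer(0),
      regimen = character(0), indication = character(0),
      cerebral_metastasis = logical(0), enrolled_at = as.Date(character(0)),
      discontinued_at = as.Date(character(0)),
      discontinuation_reason = character(0)
    ),
    questionnaires = q, iraes = empty_iraes(),
    visits = tibble::tibble(
      patient_id = character(0), visit_date = as.Date(character(0))
    ),
    ground_truth = tibble::tibble(
      questionnaire_id = character(0), gt_cause = character(0),
      gt_signature_irae = character(0)
    ),
    item_set = item_set
  )
}

#' Achievable detection performance implied by ground truth
#'
#' For a simulated bundle, the generation labels say which events carry a
#' detectable symptom signature; the fraction of such events is the
#' sensitivity the evaluation module should recover, up to coincidental
#' detection by injected false alerts.
#'
#' @param bundle A simulated [cohort_bundle()] (must carry ground truth).
#' @return A tibble `name`, `point`, `numerator`, `denominator` with the
#'   achievable sensitivity over all grade >=2 events and over symptomatic
#'   ones.
#' @export
ground_truth_metrics <- function(bundle) {
  if (is.null(bundle$ground_truth) || !("gt_detectable" %in% names(bundle$iraes))) {
    abort("bundle carries no ground truth (not simulated?)",
      class = "eprotriage_validation_error"
    )
  }
  ev <- dplyr::filter(bundle$iraes, ctcae_grade >= 2)
  sym <- dplyr::filter(ev, symptomatic)
  mk <- function(name, x) {
    tibble::tibble(
      name = name,
      point = if (nrow(x) == 0) NA_real_ else mean(x$gt_detectable),
      numerator = sum(x$gt_detectable), denominator = nrow(x)
    )
  }
  dplyr::bind_rows(
    mk("achievable_sensitivity", ev),
    mk("achievable_sensitivity_symptomatic", sym)
  )
}
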