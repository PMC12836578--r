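# Alert-to-IrAE linkage and the time-saved computation.

base_q <- function() {
  dplyr::bind_rows(
    make_q("P1", "Q1", "2021-03-01 10:00", rash = 2),
    make_q("P1", "Q0", "2021-02-10 10:00")
  )
}

test_that("a related alert preceding diagnosis detects the event with its lead time", {
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-04")
  lk <- link_detections(base_q(), iraes)
  expect_equal(lk$links$detecting_questionnaire, "Q1")
  expect_equal(lk$links$lead_days, 3L)
  expect_true(is.na(lk$links$miss_reason))
  lab <- lk$labels
  expect_equal(lab$label[lab$questionnaire_id == "Q1"], "alert_detecting")
  expect_equal(lab$label[lab$questionnaire_id == "Q0"], "green")
})

test_that("an alert with only unrelated symptoms does not detect the event", {
  q <- make_q("P1", "Q1", "2021-03-01 10:00", headache = 2)
  iraes <- make_irae("E1", "P1", "colitis_digestive", 2, "2021-03-04")
  lk <- link_detections(q, iraes)
  expect_true(is.na(lk$links$detecting_questionnaire))
  expect_equal(lk$links$miss_reason, "symptoms_not_reported")
  expect_equal(lk$labels$label, "alert_false")
})

test_that("only the first of successive qualifying alerts detects; later ones are prior-IrAE", {
  q <- dplyr::bind_rows(
    make_q("P1", "Q1", "2021-03-01 10:00", rash = 2),
    make_q("P1", "Q2", "2021-03-03 10:00", rash = 2)
  )
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-05")
  lk <- link_detections(q, iraes)
  expect_equal(lk$links$detecting_questionnaire, "Q1")
  lab <- setNames(lk$labels$label, lk$labels$questionnaire_id)
  expect_equal(lab[["Q1"]], "alert_detecting")
  expect_equal(lab[["Q2"]], "alert_prior_irae")
})

test_that("same-day ties break on the lower questionnaire id", {
  q <- dplyr::bind_rows(
    make_q("P1", "Q2", "2021-03-01 08:00", rash = 2),
    make_q("P1", "Q1", "2021-03-01 15:00", rash = 2)
  )
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-04")
  lk <- link_detections(q, iraes)
  expect_equal(lk$links$detecting_questionnaire, "Q1")
})

test_that("related alerts shortly after diagnosis are labeled prior-IrAE, not false", {
  q <- make_q("P1", "Q1", "2021-03-10 10:00", rash = 2)
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-04")
  lk <- link_detections(q, iraes)
  expect_equal(lk$labels$label, "alert_prior_irae")
})

test_that("miss reasons follow the blood/no-questionnaire/not-in-instrument/not-reported order", {
  q <- dplyr::bind_rows(
    make_q("P1", "Q1", "2021-03-01 10:00"),
    make_q("P2", "Q2", "2021-01-01 10:00")
  )
  iraes <- dplyr::bind_rows(
    make_irae("E1", "P1", "thyroiditis", 2, "2021-03-04",
      symptomatic = FALSE, related_items = ""
    ),
    make_irae("E2", "P2", "colitis_digestive", 2, "2021-03-20"), # no q in window
    make_irae("E3", "P1", "hyperlipasemia", 2, "2021-03-04"), # maps to no item
    make_irae("E4", "P1", "hepatitis", 2, "2021-03-04") # items present, not reported
  )
  lk <- link_detections(q, iraes)
  got <- setNames(lk$links$miss_reason, lk$links$irae_id)
  expect_equal(got[["E1"]], "blood_disorder_no_clinical_impact")
  expect_equal(got[["E2"]], "questionnaire_not_completed")
  expect_equal(got[["E3"]], "symptoms_not_in_questionnaire")
  expect_equal(got[["E4"]], "symptoms_not_reported")
})

test_that("grade 1 events are ignored and one questionnaire may detect two events", {
  q <- make_q("P1", "Q1", "2021-03-01 10:00", rash = 2, diarrhea = 2)
  iraes <- dplyr::bind_rows(
    make_irae("E1", "P1", "skin_toxicity", 1, "2021-03-02"), # grade 1: dropped
    make_irae("E2", "P1", "skin_toxicity", 2, "2021-03-03"),
    make_irae("E3", "P1", "colitis_digestive", 3, "2021-03-04")
  )
  lk <- link_detections(q, iraes)
  expect_equal(nrow(lk$links), 2)
  expect_equal(lk$links$detecting_questionnaire, c("Q1", "Q1"))
})

test_that("an alert outside the linkage window does not qualify", {
  q <- make_q("P1", "Q1", "2021-01-01 10:00", rash = 2)
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-04")
  lk <- link_detections(q, iraes, window_days = 30)
  expect_true(is.na(lk$links$detecting_questionnaire))
  lk2 <- link_detections(q, iraes, window_days = 90)
  expect_equal(lk2$links$detecting_questionnaire, "Q1")
})

test_that("linkage agrees with the exhaustive pairwise oracle on random small cohorts", {
  for (s in 1:12) {
    set.seed(3000 + s)
    coh <- random_linkage_cohort(n_q = sample(5:20, 1), n_irae = sample(1:6, 1))
    lk <- link_detections(coh$questionnaires, coh$iraes)
    oracle <- oracle_link(coh$questionnaires, coh$iraes)
    expect_equal(
      setNames(lk$links$detecting_questionnaire, lk$links$irae_id),
      oracle$detecting
    )
    expect_equal(setNames(lk$links$lead_days, lk$links$irae_id), oracle$lead)
    expect_equal(
      setNames(lk$labels$label, lk$labels$questionnaire_id),
      oracle$label[lk$labels$questionnaire_id]
    )
    # detection implies lead within [0, window]
    ld <- lk$links$lead_days[!is.na(lk$links$detecting_questionnaire)]
    expect_true(all(ld >= 0 & ld <= 30))
  }
})

test_that("days saved is the gap from diagnosis to the next visit, floored at zero", {
  visits <- as.Date(c("2021-02-15", "2021-03-08", "2021-04-19"))
  # diagnosis on the visit day itself: nothing saved
  expect_equal(time_saved(as.Date("2021-03-05"), as.Date("2021-03-08"), visits), 0L)
  # diagnosis 20 days before the next visit
  expect_equal(time_saved(as.Date("2021-03-10"), as.Date("2021-03-30"), visits), 20L)
  # next visit 7 days after detection, diagnosis 3 days after detection
  expect_equal(
    time_saved(as.Date("2021-03-01"), as.Date("2021-03-04"), as.Date("2021-03-08")),
    4L
  )
  # no later visit: undefined
  expect_true(is.na(time_saved(as.Date("2021-05-01"), as.Date("2021-05-02"), visits)))
})

test_that("add_time_saved wires detection dates, diagnoses, and schedules together", {
  q <- base_q()
  iraes <- make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-04")
  visits <- tibble::tibble(
    patient_id = "P1",
    visit_date = as.Date(c("2021-02-15", "2021-03-08"))
  )
  lk <- link_detections(q, iraes)
  links <- add_time_saved(lk, q, visits)
  expect_equal(links$days_saved, 4L) # visit 03-08 minus diagnosis 03-04
})
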