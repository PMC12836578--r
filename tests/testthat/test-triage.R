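test_that("grade bucketing follows the absent/moderate/severe rule and overrides", {
  expect_equal(bucket_grade(0, "fatigue"), "absent_slight")
  expect_equal(bucket_grade(1, "fatigue"), "absent_slight")
  expect_equal(bucket_grade(2, "diarrhea"), "moderate")
  expect_equal(bucket_grade(3, "rash"), "severe")
  expect_equal(bucket_grade(4, "diarrhea"), "severe")
  pol <- scoring_policy(escalation_overrides = c(diarrhea = 2))
  expect_equal(bucket_grade(2, "diarrhea", pol), "severe")
  expect_equal(bucket_grade(1, "diarrhea", pol), "absent_slight")
  expect_equal(bucket_grade(2, "fatigue", pol), "moderate")
  expect_error(bucket_grade(2, "itching"), class = "eprotriage_validation_error")
})

test_that("triage colors match the published rule on canonical cases", {
  t0 <- "2021-01-05 10:00"
  cases <- list(
    list(q = make_q("P1", "Q1", t0), color = "green", m = 0, s = 0),
    list(
      q = make_q("P1", "Q2", t0, fatigue = 2, general_pain = 2),
      color = "orange", m = 2, s = 0
    ),
    list(
      q = make_q("P1", "Q3", t0, fatigue = 2, rash = 2, diarrhea = 2),
      color = "red", m = 3, s = 0
    ),
    list(
      q = make_q("P1", "Q4", t0, shortness_of_breath = 3),
      color = "red", m = 0, s = 1
    ),
    list(q = make_q("P1", "Q5", t0, headache = 2), color = "orange", m = 1, s = 0)
  )
  for (cs in cases) {
    sc <- score_questionnaire(cs$q)
    expect_equal(as.character(sc$color), cs$color)
    expect_equal(sc$n_moderate, as.integer(cs$m))
    expect_equal(sc$n_severe, as.integer(cs$s))
  }
})

test_that("an escalation override turns a grade-2 report into a red score", {
  q <- make_q("P1", "Q1", "2021-01-05 10:00", diarrhea = 2)
  expect_equal(as.character(score_questionnaire(q)$color), "orange")
  pol <- scoring_policy(escalation_overrides = c(diarrhea = 2))
  sc <- score_questionnaire(q, pol)
  expect_equal(as.character(sc$color), "red")
  expect_equal(sc$n_severe, 1L)
  expect_equal(sc$n_moderate, 0L)
})

test_that("scoring agrees with a brute-force oracle and partitions all colors", {
  set.seed(101)
  q <- random_questionnaires(400)
  sc <- score_questionnaires(q)
  expect_equal(nrow(sc), 400)
  expect_equal(sum(table(sc$color)), 400) # total partition
  for (j in seq_len(nrow(q))) {
    o <- oracle_score_row(q[j, ])
    expect_equal(as.character(sc$color[j]), o$color)
    expect_equal(sc$n_moderate[j], o$n_moderate)
    expect_equal(sc$n_severe[j], o$n_severe)
  }
  # and under a random escalation policy
  pol <- scoring_policy(escalation_overrides = c(diarrhea = 2, fever = 2))
  sc2 <- score_questionnaires(q, pol)
  for (j in seq_len(nrow(q))) {
    o <- oracle_score_row(q[j, ], pol)
    expect_equal(as.character(sc2$color[j]), o$color)
  }
})

test_that("raising any single grade never decreases the color", {
  set.seed(202)
  q <- random_questionnaires(300)
  items <- standard_item_set()
  pols <- list(
    scoring_policy(),
    scoring_policy(escalation_overrides = c(diarrhea = 2)),
    scoring_policy(escalation_overrides = c(fatigue = 3, rash = 2))
  )
  for (pol in pols) {
    before <- score_questionnaires(q, pol)$color
    bumped <- q
    pick <- sample(items$item_id, nrow(q), TRUE)
    for (j in seq_len(nrow(q))) {
      id <- pick[j]
      ceiling_j <- items$max_grade[items$item_id == id]
      bumped[[id]][j] <- min(ceiling_j, bumped[[id]][j] + 1L)
    }
    after <- score_questionnaires(bumped, pol)$color
    expect_true(all(as.integer(after) >= as.integer(before)))
  }
})

test_that("alert deadlines implement the 24-48h orange window and immediate red", {
  # orange received Tue 10:00 inside working hours
  sc <- score_questionnaire(make_q("P1", "Q1", "2021-01-05 10:00", fatigue = 2))
  al <- raise_alert(sc)
  expect_equal(al$raised_at, utc("2021-01-05 10:00"))
  expect_equal(al$respond_by_earliest, utc("2021-01-06 10:00"))
  expect_equal(al$respond_by_latest, utc("2021-01-07 10:00"))
  expect_equal(as.numeric(al$respond_by_latest - al$respond_by_earliest, units = "hours"), 24)

  # red received Tue 20:00, after closing: effective receipt Wed 09:00
  sc <- score_questionnaire(make_q("P1", "Q2", "2021-01-05 20:00", rash = 3))
  al <- raise_alert(sc)
  expect_equal(al$respond_by_earliest, utc("2021-01-06 09:00"))
  expect_equal(al$respond_by_latest, al$respond_by_earliest)

  # before opening: same day 09:00
  sc <- score_questionnaire(make_q("P1", "Q3", "2021-01-05 07:30", rash = 3))
  expect_equal(raise_alert(sc)$respond_by_earliest, utc("2021-01-05 09:00"))

  # green raises nothing
  sc <- score_questionnaire(make_q("P1", "Q4", "2021-01-05 10:00"))
  expect_null(raise_alert(sc))
})

test_that("weekend-closed policies defer receipt to Monday opening", {
  pol <- scoring_policy(weekend_closed = TRUE)
  # Friday 2021-01-08 20:00 -> next opening Monday 09:00
  expect_equal(
    effective_receipt(utc("2021-01-08 20:00"), pol),
    utc("2021-01-11 09:00")
  )
  # default policy treats every day as working
  expect_equal(
    effective_receipt(utc("2021-01-08 20:00")),
    utc("2021-01-09 09:00")
  )
})

test_that("reminders repeat every 7 days until completion or window end", {
  t0 <- utc("2021-01-04 09:00")
  expect_length(reminder_schedule(t0, completed_at = t0 + 2 * 86400), 0)
  expect_equal(
    reminder_schedule(t0, until = t0 + 16 * 86400),
    c(t0 + 7 * 86400, t0 + 14 * 86400)
  )
  expect_equal(
    reminder_schedule(t0, completed_at = t0 + 9 * 86400),
    t0 + 7 * 86400
  )
  expect_length(reminder_schedule(t0, until = t0 + 30 * 86400, max_reminders = 2), 2)
})

test_that("monthly calls fall on the 28-day grid truncated at follow-up end", {
  d0 <- as.Date("2021-01-01")
  expect_length(monthly_call_schedule(d0, d0 + 10), 0)
  expect_equal(
    monthly_call_schedule(d0, d0 + 90),
    d0 + c(28, 56, 84)
  )
  expect_length(monthly_call_schedule(d0, d0), 0)
})
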