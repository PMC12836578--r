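# Wilson intervals, confusion counts, diagnostic metrics, cause taxonomy.

test_that("wilson_ci matches the score-test interval and behaves at the boundaries", {
  grid <- expand.grid(x = c(0, 1, 5, 27, 50), n = c(10, 69, 500))
  grid <- grid[grid$x <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]
    n <- grid$n[i]
    ours <- wilson_ci(x, n)
    ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
  expect_error(wilson_ci(1, 0))
  expect_error(wilson_ci(5, 3))
})

test_that("wilson interval contains the point estimate and widens with the level", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    ci95 <- wilson_ci(x, n, 0.95)
    ci99 <- wilson_ci(x, n, 0.99)
    p <- x / n
    expect_true(ci95[1] <= p && p <= ci95[2])
    expect_true(ci99[1] <= ci95[1] && ci99[2] >= ci95[2])
    expect_true(all(c(ci95, ci99) >= 0 & c(ci95, ci99) <= 1))
  }
})

test_that("mixed-unit confusion counts derive TN as greens minus event-level FN", {
  cc <- confusion_counts_from_totals(27, 42, 761, 4394, prior_quest = 25)
  expect_equal(cc$tn_quest, 4352L)
  expect_s3_class(cc, "confusion_counts")
  # symptomatic-only variant of the same cohort: 31 blood-only misses removed
  cc_sym <- confusion_counts_from_totals(27, 42 - 31, 761, 4394, prior_quest = 25)
  expect_equal(cc_sym$tp_irae, 27L)
  expect_equal(cc_sym$fn_irae, 11L)
  expect_equal(cc_sym$tn_quest, 4383L)
  expect_error(
    confusion_counts_from_totals(1, 20, 0, 10),
    regexp = "inconsistent cohort", class = "eprotriage_validation_error"
  )
})

test_that("confusion counts from a linkage respect the symptomatic-only switch", {
  q <- dplyr::bind_rows(
    make_q("P1", "Q1", "2021-03-01 10:00", rash = 2),
    make_q("P1", "Q2", "2021-03-02 10:00", fatigue = 2), # false alert
    make_q("P1", "Q3", "2021-02-01 10:00") # green
  )
  iraes <- dplyr::bind_rows(
    make_irae("E1", "P1", "skin_toxicity", 2, "2021-03-03"),
    make_irae("E2", "P1", "thyroiditis", 2, "2021-03-20",
      symptomatic = FALSE, related_items = ""
    )
  )
  lk <- link_detections(q, iraes)
  cc <- confusion_counts(lk)
  expect_equal(cc$tp_irae, 1L)
  expect_equal(cc$fn_irae, 1L)
  expect_equal(cc$fp_quest, 1L)
  expect_equal(cc$green_quest, 1L)
  expect_equal(cc$tn_quest, 0L)
  cc_sym <- confusion_counts(lk, symptomatic_only = TRUE)
  expect_equal(cc_sym$fn_irae, 0L)
  expect_equal(cc_sym$tn_quest, 1L)
})

test_that("an empty cohort yields all-zero counts without errors", {
  items <- standard_item_set()
  q <- empty_questionnaire("P1", "Q1", utc("2021-01-04 09:00"))[0, ]
  iraes <- make_irae("E1", "P1", "hepatitis", 2, "2021-01-01")[0, ]
  lk <- link_detections(q, iraes)
  cc <- confusion_counts(lk)
  expect_equal(
    c(cc$tp_irae, cc$fn_irae, cc$fp_quest, cc$green_quest, cc$tn_quest),
    rep(0L, 5)
  )
})

test_that("diagnostic metrics reproduce known ratios and flag empty denominators", {
  m <- diagnostic_metrics(confusion_counts_from_totals(27, 42, 761, 4394))
  get <- function(nm, col) m[[col]][m$name == nm]
  expect_equal(round(get("sensitivity", "point"), 3), 0.391)
  expect_equal(round(get("ppv", "point"), 3), 0.034)
  expect_equal(get("specificity", "numerator"), 4352L)
  expect_equal(get("specificity", "denominator"), 5113L)
  expect_true(all(m$ci_low <= m$point & m$point <= m$ci_high))
  expect_true(all(m$point >= 0 & m$point <= 1))

  perfect <- diagnostic_metrics(confusion_counts_from_totals(1, 0, 0, 10))
  expect_equal(perfect$point[perfect$name == "sensitivity"], 1)
  expect_equal(perfect$point[perfect$name == "npv"], 1)

  degenerate <- diagnostic_metrics(confusion_counts_from_totals(0, 0, 0, 0))
  expect_true(is.na(degenerate$point[degenerate$name == "sensitivity"]))

  exact <- diagnostic_metrics(confusion_counts_from_totals(27, 42, 761, 4394),
    ci_method = "exact"
  )
  cp <- stats::binom.test(27, 69)$conf.int
  expect_equal(exact$ci_low[exact$name == "sensitivity"], cp[1])
})

test_that("cause summary covers the six-way taxonomy and demands full annotation", {
  labels <- tibble::tibble(
    questionnaire_id = sprintf("Q%d", 1:5),
    color = factor(c("orange", "orange", "red", "green", "orange"),
      levels = c("green", "orange", "red")
    ),
    label = c("alert_false", "alert_false", "alert_false", "green", "alert_detecting"),
    followed_by_irae = FALSE
  )
  causes <- tibble::tibble(
    questionnaire_id = c("Q1", "Q2", "Q3"),
    cause = c("input_error", "input_error", "tumor_burden")
  )
  cs <- cause_summary(labels, causes)
  expect_equal(nrow(cs), 6) # all categories visible
  expect_equal(sum(cs$n), 3)
  expect_equal(cs$proportion[cs$cause == "input_error"], 2 / 3)
  expect_equal(sum(cs$proportion), 1)

  # a single annotated false alert
  one <- cause_summary(labels[3:4, ], causes[3, ])
  expect_equal(one$proportion[one$cause == "tumor_burden"], 1)

  # no false alerts at all -> empty summary
  expect_equal(nrow(cause_summary(labels[4:5, ], causes)), 0)

  # missing annotation is an error naming the questionnaire
  expect_error(cause_summary(labels, causes[1:2, ]),
    regexp = "Q3", class = "eprotriage_validation_error"
  )
})
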