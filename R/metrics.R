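# Confusion counts and diagnostic metrics.
#
# The confusion scheme is deliberately mixed-unit, matching how an ePRO
# alert system is audited in practice: true and false positives are counted
# per adverse event (a detected / undetected grade >=2 IrAE ... per event;
# a false alert per questionnaire), true negatives per questionnaire. The
# true-negative count is derived as greens minus event-level false
# negatives, the unique convention that makes all four headline metrics
# internally consistent.

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval. Unlike the Wald interval it is well behaved
#' at the boundaries: `successes = 0` gives a lower bound of exactly 0 and
#' `successes = trials` an upper bound of exactly 1.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials > 0`. Vectorized.
#' @param level Confidence level, default 0.95.
#' @return For scalar input, a named numeric `c(low, high)`; for vector
#'   input, a two-column matrix.
#' @examples
#' wilson_ci(27, 69)
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (any(trials <= 0)) abort("trials must be positive")
  if (any(successes < 0 | successes > trials)) {
    abort("successes must lie in [0, trials]")
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  low <- pmax(0, center - half)
  high <- pmin(1, center + half)
  # analytically exact at the boundaries; avoids sub-epsilon noise
  low[successes == 0] <- 0
  high[successes == trials] <- 1
  if (length(low) == 1) c(low = low, high = high) else cbind(low = low, high = high)
}

new_confusion_counts <- function(tp_irae, fn_irae, fp_quest, green_quest,
                                 prior_quest = 0L, n_detecting_quest = NA_integer_,
                                 scheme = "mixed") {
  tn_quest <- green_quest - fn_irae
  if (any(c(tp_irae, fn_irae, fp_quest, green_quest, prior_quest) < 0)) {
    abort("confusion counts must be non-negative")
  }
  if (tn_quest < 0) {
    abort("inconsistent cohort: more undetected IrAEs than green questionnaires",
      class = "eprotriage_validation_error"
    )
  }
  structure(
    list(
      tp_irae = as.integer(tp_irae), fn_irae = as.integer(fn_irae),
      fp_quest = as.integer(fp_quest), green_quest = as.integer(green_quest),
      tn_quest = as.integer(tn_quest), prior_quest = as.integer(prior_quest),
      n_detecting_quest = as.integer(n_detecting_quest), scheme = scheme
    ),
    class = "confusion_counts"
  )
}

#' Build confusion counts from a detection linkage
#'
#' Default (`scheme = "mixed"`): true positives are detected grade >=2
#' IrAEs, false negatives undetected ones, false positives the alert
#' questionnaires linked to no event, greens the green questionnaires, and
#' true negatives are derived as `green_quest - fn_irae`. Alerts tied to an
#' already-diagnosed event (`alert_prior_irae`) are excluded from every
#' cell. `symptomatic_only = TRUE` drops asymptomatic blood-test events
#' from the event-level cells, the subset an ePRO instrument can in
#' principle see.
#'
#' `scheme = "questionnaire"` is a pure questionnaire-level alternative for
#' sensitivity analyses: TP = detecting questionnaires, FN = green
#' questionnaires followed by a grade >=2 event within the linkage window.
#'
#' @param linkage A `detection_linkage` from [link_detections()], or a
#'   plain list with `links` and `labels` tibbles of the same shape.
#' @param symptomatic_only Drop blood-only events from TP/FN.
#' @param scheme `"mixed"` (default) or `"questionnaire"`.
#' @return An object of class `confusion_counts`.
#' @examples
#' # counts alone can also be assembled directly:
#' cc <- confusion_counts_from_totals(27, 42, 761, 4394, prior_quest = 25)
#' diagnostic_metrics(cc)
#' @export
confusion_counts <- function(linkage, symptomatic_only = FALSE,
                             scheme = c("mixed", "questionnaire")) {
  scheme <- match.arg(scheme)
  links <- linkage$links
  labels <- linkage$labels
  if (symptomatic_only) links <- dplyr::filter(links, symptomatic)
  detected <- !is.na(links$detecting_questionnaire)
  green_quest <- sum(labels$label == "green")
  fp_quest <- sum(labels$label == "alert_false")
  prior_quest <- sum(labels$label == "alert_prior_irae")
  n_detecting <- sum(labels$label == "alert_detecting")
  if (scheme == "mixed") {
    new_confusion_counts(
      tp_irae = sum(detected), fn_irae = sum(!detected),
      fp_quest = fp_quest, green_quest = green_quest,
      prior_quest = prior_quest, n_detecting_quest = n_detecting,
      scheme = scheme
    )
  } else {
    fn_q <- sum(labels$label == "green" & labels$followed_by_irae)
    new_confusion_counts(
      tp_irae = n_detecting, fn_irae = fn_q,
      fp_quest = fp_quest, green_quest = green_quest,
      prior_quest = prior_quest, n_detecting_quest = n_detecting,
      scheme = scheme
    )
  }
}

#' @rdname confusion_counts
#' @param tp_irae,fn_irae,fp_quest,green_quest,prior_quest Aggregate counts
#'   as defined above, for building a `confusion_counts` from published
#'   totals rather than patient-level data.
#' @export
confusion_counts_from_totals <- function(tp_irae, fn_irae, fp_quest,
                                         green_quest, prior_quest = 0L) {
  new_confusion_counts(tp_irae, fn_irae, fp_quest, green_quest, prior_quest)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> (", x$scheme, " scheme)\n", sep = "")
  cat("  TP (events):        ", x$tp_irae, "\n")
  cat("  FN (events):        ", x$fn_irae, "\n")
  cat("  FP (questionnaires):", x$fp_quest, "\n")
  cat("  TN (questionnaires):", x$tn_quest, " = ", x$green_quest, "greens -",
    x$fn_irae, "FN\n")
  if (x$prior_quest > 0) cat("  excluded prior-IrAE alerts:", x$prior_quest, "\n")
  invisible(x)
}

#' Diagnostic metrics with confidence intervals
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, each with a
#' binomial confidence interval on its own numerator/denominator. A metric
#' with a zero denominator is returned as `NA`, never fabricated.
#'
#' @param cc A `confusion_counts`.
#' @param level Confidence level, default 0.95.
#' @param ci_method `"wilson"` (default, closed form) or `"exact"`
#'   (Clopper--Pearson via [stats::binom.test()]).
#' @return A tibble: `name`, `point`, `ci_low`, `ci_high`, `numerator`,
#'   `denominator`, `level`.
#' @examples
#' diagnostic_metrics(confusion_counts_from_totals(27, 42, 761, 4394))
#' @export
diagnostic_metrics <- function(cc, level = 0.95,
                               ci_method = c("wilson", "exact")) {
  ci_method <- match.arg(ci_method)
  rows <- list(
    sensitivity = c(cc$tp_irae, cc$tp_irae + cc$fn_irae),
    specificity = c(cc$tn_quest, cc$tn_quest + cc$fp_quest),
    ppv = c(cc$tp_irae, cc$tp_irae + cc$fp_quest),
    npv = c(cc$tn_quest, cc$tn_quest + cc$fn_irae)
  )
  purrr::imap_dfr(rows, function(nd, nm) {
    num <- nd[1]
    den <- nd[2]
    if (den == 0) {
      return(tibble::tibble(
        name = nm, point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        numerator = num, denominator = den, level = level
      ))
    }
    ci <- if (ci_method == "wilson") {
      wilson_ci(num, den, level)
    } else {
      as.numeric(binom.test(num, den, conf.level = level)$conf.int)
    }
    tibble::tibble(
      name = nm, point = num / den, ci_low = ci[1], ci_high = ci[2],
      numerator = num, denominator = den, level = level
    )
  })
}

#' False-alert cause taxonomy
#'
#' @return The six annotation categories for alerts with no associated
#'   grade >=2 IrAE, in reporting order.
#' @export
false_alert_causes <- function() {
  c(
    "functional_nonspecific", "previous_condition", "independent_condition",
    "input_error", "overestimated_grade1", "tumor_burden"
  )
}

#' Summarize false-alert causes
#'
#' Tallies the annotated cause of every `alert_false` questionnaire.
#' Proportions are over the false-alert total; categories never observed
#' appear with zero counts so the six-way taxonomy stays visible.
#'
#' @param labels `labels` tibble from [link_detections()].
#' @param causes Tibble `questionnaire_id`, `cause` (chart-review or
#'   simulator ground-truth annotations).
#' @return A tibble `cause`, `n`, `proportion`.
#' @export
cause_summary <- function(labels, causes) {
  false_ids <- labels$questionnaire_id[labels$label == "alert_false"]
  if (length(false_ids) == 0) {
    return(tibble::tibble(
      cause = character(0), n = integer(0), proportion = numeric(0)
    ))
  }
  ann <- setNames(causes$cause, causes$questionnaire_id)
  missing_ann <- false_ids[!(false_ids %in% names(ann)) | is.na(ann[false_ids])]
  if (length(missing_ann) > 0) {
    abort(paste0(
      "false-alert questionnaires without cause annotation: ",
      toString(head(missing_ann, 10))
    ), class = "eprotriage_validation_error")
  }
  got <- factor(ann[false_ids], levels = false_alert_causes())
  tab <- table(got)
  tibble::tibble(
    cause = names(tab),
    n = as.integer(tab),
    proportion = as.integer(tab) / length(false_ids)
  )
}
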