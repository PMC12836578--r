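---
title: "Triage scoring and alert evaluation for ePRO-based IrAE monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage scoring and alert evaluation for ePRO-based IrAE monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprotriage)
```

## The monitoring problem

Immune checkpoint inhibitors cause immune-related adverse events (IrAEs)
with unpredictable, sometimes delayed onset, while scheduled melanoma
clinic visits are 3–6 weeks apart. A weekly electronic patient-reported
outcome (ePRO) questionnaire narrows that surveillance gap: 11 symptoms
suggestive of IrAEs (fever per CTCAE v5 plus ten PRO-CTCAE-inspired
items), each self-graded 0–3, or 0–4 for nausea/vomiting and diarrhea,
whose CTCAE analogues extend to grade 4 in a form a patient can
self-assess. The per-item ceilings are configurable
(`symptom_item_set()`); because the triage rule only distinguishes
grade ≤ 1 / = 2 / ≥ 3, the ceiling assignment can never change a score,
only the range validation.

## Triage rule

Grades are bucketed absent/slight (0–1), moderate (2), severe (3–4).
With $m$ moderate and $s$ severe items, the color is

$$
\mathrm{color} =
\begin{cases}
\text{green} & m = 0,\ s = 0\\
\text{orange} & 1 \le m \le 2,\ s = 0\\
\text{red} & s \ge 1 \text{ or } m \ge 3.
\end{cases}
$$

The rule is total and deterministic — the three cases partition every
possible questionnaire, and increasing any single grade can only move the
color up the ordering green < orange < red. Both properties are enforced
as property-style tests against an independent brute-force scorer.

**Escalation overrides.** A policy may declare, per item, a minimum grade
that is force-bucketed severe (e.g. `c(diarrhea = 2)` so that any grade-2
diarrhea report produces a red score, the variant motivated by
potentially severe immune colitis). Overrides act at the *bucketing* step
rather than recoloring the final score, so the reported $m$/$s$ counts
remain interpretable and the monotonicity property is preserved.

**Workflow timing.** Orange alerts must be answered within 24–48 h of
effective receipt, red alerts immediately. Effective receipt shifts
out-of-hours questionnaires to the next 09:00 opening; the monitoring
service ran every day, so weekends are working days by default
(`weekend_closed = TRUE` gives the Monday-deferral variant — the source
workflow states working hours but no weekend rule, so both are
expressible and the simpler one is the default). Completion reminders
repeat every 7 days until completion (the workflow specifies the first
reminder; we let it recur at the instrument's natural weekly cadence,
with a configurable cap). The monthly nurse call is one call per 28 days
from enrollment; a calendar-month anchor was rejected because it makes
schedules depend on month lengths.

## Linking alerts to IrAEs

An IrAE of CTCAE grade ≥ 2 counts as *correctly detected* if some
orange/red questionnaire of the same patient

1. was completed on or before the diagnosis date,
2. at most `window_days` (default 30) before it, and
3. reports at least one moderate/severe symptom in the event's related
   item set.

The window is not stated by the source workflow; 30 days covers the
observed 0–25-day alert-to-diagnosis intervals with margin and is
configurable. Relatedness is a category→item configuration file
(`relatedness_default.yaml`), not code; a per-event `related_items`
annotation overrides it (`NA` = use the map, `"none"` = explicitly no
reportable symptom — the token exists because an empty CSV field cannot
be distinguished from missing on read). Among qualifying alerts only the
earliest detects, so an event is never counted twice; same-day ties break
on the lower questionnaire id, deterministically. Later qualifying
alerts, and alerts echoing the event's related symptoms within the window
*after* diagnosis, are labeled `alert_prior_irae` and excluded from the
confusion counts — they concern an already-known event. Undetected events
get one miss reason, assigned in priority order: asymptomatic blood-test
disorder; no questionnaire in the window; related symptoms not in the
instrument; symptoms present in the instrument but not reported.

## Confusion counts and metrics

The audit convention is mixed-unit: detection successes and failures are
events (TP, FN), false alarms and reassurance are questionnaires (FP,
green), and TN is *derived* as greens − FN. This is the unique scheme
under which all four headline metrics of the development cohort are
internally consistent (sensitivity 27/69, specificity 4352/5113, PPV
27/788, NPV 4352/4394, where 4352 = 4394 − 42). A pure
questionnaire-level scheme (`scheme = "questionnaire"`; FN = green weeks
followed by an event within the window) is provided for sensitivity
analyses. `symptomatic_only = TRUE` removes asymptomatic blood-test
events from the event-level cells — the subset an ePRO instrument can in
principle see. A cohort with more missed events than green questionnaires
would make the derived TN negative and is rejected as inconsistent rather
than clamped.

All proportions carry Wilson score intervals, which are closed-form,
boundary-exact (0 successes → lower bound exactly 0) and reproduce the
development cohort's printed sensitivity lower bound (28.5%); the printed
upper bound (50.91%) differs from Wilson's 50.93% in the second decimal
and the source's CI method is unnamed, so the upper bound is only
asserted to 5×10⁻⁴. Clopper–Pearson (`ci_method = "exact"`) is available.
A zero-denominator metric is reported as `NA`, never fabricated. One
arithmetic ambiguity is left unresolved on purpose: the symptomatic-only
NPV is 4383/4394 = 99.7% under the 11 symptomatic misses, while the
source prints 99.8% (consistent with 10); both computations are exposed
via `confusion_counts(symptomatic_only = TRUE)` and neither is asserted.

*Days saved* for a detected event is the gap from diagnosis to the first
scheduled visit strictly after the detecting questionnaire, floored at 0
and undefined (excluded from summaries) when no later visit exists.

## The cohort simulator

`simulate_cohort()` draws, from a single seed, patients (enrollment,
truncated log-normal follow-up with median 46 weeks over 1–227,
sex/age/regimen/indication mix), a weekly questionnaire grid with
Bernoulli(0.89) completion and uniform time of day, visit schedules every
42 days, and an IrAE registry: 36.8% of patients affected, extra events
Poisson(0.38), category weights proportional to the development
registry's 69 events, 44.9% asymptomatic blood-test findings, 24.6%
grade 3/4 (×3 odds-style multiplier for combination-regimen patients,
reflecting their higher severe-toxicity rate).

Detection structure is generated, not emergent: a symptomatic event
leaves, with probability `symptom_signature_strength` (default 0.80), a
symptom signature — its related items raised to grade 2 (one to grade 3
for a grade 3/4 event) — on the questionnaire of the week preceding
diagnosis, if that week's questionnaire was completed. The default 0.80
was calibrated once so that the expected symptomatic detection rate,
strength × adherence ≈ 0.71, and the overall rate,
(1 − blood-only fraction) × 0.712 ≈ 0.39, match the development cohort's
observed performance. Two deliberate consistency choices keep that
generating value analytically clean: blood-only events carry
`related_items = "none"` (a lab finding has no reportable symptom, and in
the development cohort none was ever alert-detected), and symptomatic
events only draw categories whose related items exist in the instrument
(hyperlipasemia and nephritis map to no item and so are drawn
asymptomatic). Signature-free questionnaires become false alerts with
probability 0.146 — red with probability 0.158 — elevating one to three
items drawn from fatigue/general-pain-heavy weights, with the generating
cause drawn from the six-category mix (0.323/0.187/0.184/0.146/0.083/
0.078) and recorded as ground truth. Background weeks carry only
grade-0/1 noise (each item grade 1 with probability 0.08), which can
never alert, so the alert rate decomposes exactly into injected false
alerts plus signatures.

What the simulator does *not* emulate: IrAE onset hazard shape (uniform
over follow-up), diagnosis dates anchored to clinic visits (real
blood-test IrAEs surface *at* visits, which is why the development
cohort's mean days-saved, 4.1, is much smaller than the simulator's),
informative dropout, per-item grade distributions on non-alert weeks
(only alert-level symptom shares were available for calibration), and
symptom persistence across weeks. Passing recovery tests therefore show
that scoring, linkage and the estimators are correct on cohorts with this
generative structure — not that the instrument performs identically on
real patients.

`ground_truth_metrics()` reports the achievable sensitivity implied by
the generation labels; the evaluation estimate can only exceed it through
coincidental detection (a false alert that happens to qualify), a small
upward term accepted inside the recovery tolerance.

## Verification design and problem sizes

- Scoring: brute-force oracle equivalence and monotonicity on 10,000
  random questionnaires plus 700 under escalation policies.
- Linkage: exhaustive pairwise-scan oracle on twenty random cohorts of
  ≤ 20 questionnaires and ≤ 7 events, including tie and post-diagnosis
  cases.
- Wilson intervals: cross-checked against `stats::prop.test(correct =
  FALSE)` over a grid, plus containment/nesting properties.
- Parameter recovery: one simulated cohort of 400 patients (~19,000
  questionnaires, ~190 events, a few seconds to evaluate); estimated
  sensitivities and the six cause proportions must fall within 3
  binomial standard errors of their generating values.
- Determinism: same-seed simulations, bundles and reports are
  byte-identical.

## Known limitations

- The development cohort's patient-level records are unavailable; its
  full per-category detection table cannot be recomputed, only the
  aggregate arithmetic shipped in `reference_cohort_counts()`.
- The free-text callback request is not a score input (the workflow
  describes calls, not score changes), so a green questionnaire with a
  callback request raises no alert.
- The mixed logistic model of alert-occurrence risk factors and the
  group-comparison tests reported for the development cohort are out of
  scope: they require the unavailable patient-level data.
- Relatedness mapping is judgment encoded as configuration; a different
  map changes which alerts count as detections, and sites should review
  it before drawing conclusions.
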