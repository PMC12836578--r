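# eprotriage

Symptom-questionnaire triage and alert evaluation for remote monitoring of
immune-checkpoint-inhibitor toxicity in melanoma.

Melanoma patients on immune checkpoint inhibitors (anti-PD-1 alone or
combined with ipilimumab) develop immune-related adverse events (IrAEs)
whose onset is unpredictable and often falls between scheduled clinic
visits (3–6 weeks apart). A remote-monitoring workflow asks patients to
grade 11 IrAE-suggestive symptoms every week on a 0–3 (or 0–4) scale
adapted from CTCAE v5 / PRO-CTCAE; a deterministic rule converts each
questionnaire into a triage color and an oncology-nurse alert. This package
implements that instrument, the triage rule, the alert/reminder/monthly-call
workflow semantics, the retrospective evaluation that links alerts to
grade ≥2 IrAEs, and a seeded cohort simulator so the whole pipeline is
testable without patient data.

## The triage rule and evaluation model

Each symptom grade *g* is bucketed **absent/slight** (*g* ≤ 1),
**moderate** (*g* = 2) or **severe** (*g* ≥ 3). With *m* moderate and *s*
severe symptoms on a questionnaire:

- **green** iff *m* = 0 and *s* = 0,
- **orange** iff 1 ≤ *m* ≤ 2 and *s* = 0 — nurse calls within 24–48 h,
- **red** iff *s* ≥ 1 or *m* ≥ 3 — nurse calls immediately,

with alerts handled during working hours (09:00–16:30; out-of-hours
receipts shift to the next opening). Policy variants (e.g. forcing any
grade-2 diarrhea to red for earlier colitis capture) are expressed as
per-item escalation overrides applied at the bucketing step.

The evaluation links each grade ≥2 IrAE to the **first** preceding alert
questionnaire within a window (default 30 days) that reports a moderate or
severe symptom *related* to the event's category (configurable
category→item map). Counts follow the field's mixed-unit convention:
TP = detected IrAEs and FN = missed IrAEs (event level), FP = alert
questionnaires linked to no event and TN = green questionnaires − FN
(questionnaire level). Sensitivity, specificity, PPV and NPV each get a
Wilson score interval (Clopper–Pearson optional).

## Worked example

Headline metrics of the development cohort, recomputed from its packaged
aggregate counts (136 patients, 5202 questionnaires, 69 grade ≥2 IrAEs):

```r
library(eprotriage)
diagnostic_metrics(reference_confusion_counts())
#>         name  point ci_low ci_high numerator denominator
#>  sensitivity 0.3913 0.2848  0.5093        27          69
#>  specificity 0.8512 0.8411  0.8607      4352        5113
#>          ppv 0.0343 0.0237  0.0494        27         788
#>          npv 0.9904 0.9871  0.9929      4352        4394
```

So the instrument detected 39.1% of all grade ≥2 IrAEs (71.1% of the
symptomatic ones — asymptomatic blood-test findings are structurally
invisible to self-report), while a green week predicted the absence of an
imminent IrAE with 99.0% probability.

End-to-end on a synthetic cohort:

```r
b <- simulate_cohort(simulation_params(n_patients = 120, seed = 42))
cohort_report(b)
#> == Cohort evaluation report ==
#> 120 patients, 6508 questionnaires; linkage window 30 days
#> ...
#> Alert rate: 15.3%
#> Diagnostic metrics, all grade >=2 IrAEs:
#>   sensitivity   41.2% (21/51, 95% CI 28.8-54.8%)
#>   specificity   85.0% (5482/6452, 95% CI 84.1-85.8%)
#> ...
#> Days saved vs next visit (n=19): mean 15.4, median 16.0, range 0-35
```

The simulated alert rate, score mix and detection performance sit near the
generator's configured values (the methods vignette details the generative
model and what it does and does not emulate).

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/eprotriage.R", package="eprotriage"))')
Rscript $CLI simulate --seed 17 --n-patients 50 --out cohort/
Rscript $CLI score    --in cohort/questionnaires.csv --out scores.csv
Rscript $CLI evaluate --dir cohort/ --window 30 --out report.json
```

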