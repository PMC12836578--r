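{
  "description": "Aggregate counts from the development cohort of the monitoring system: 136 melanoma patients on immune checkpoint inhibitors followed with the weekly 11-item questionnaire (median follow-up 46 weeks). Patient-level records are not redistributable; these published totals suffice to reproduce every headline metric.",
  "n_patients": 136,
  "n_questionnaires": 5202,
  "scores": { "green": 4394, "orange": 661, "red": 122, "prior_irae_alert": 25 },
  "alerts_total": 783,
  "iraes_grade2plus": 69,
  "iraes_detected": 27,
  "iraes_missed": 42,
  "iraes_blood_only_missed": 31,
  "iraes_symptomatic": 38,
  "detecting_questionnaires": 22,
  "questionnaires_with_following_irae": 64,
  "questionnaires_with_following_symptomatic_irae": 34,
  "false_alert_questionnaires": 761,
  "greens_followed_by_irae": 35,
  "false_alert_causes": {
    "functional_nonspecific": 246,
    "previous_condition": 142,
    "independent_condition": 140,
    "input_error": 111,
    "overestimated_grade1": 63,
    "tumor_burden": 59
  }
}
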