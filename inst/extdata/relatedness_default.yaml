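# Default mapping from IrAE category to the questionnaire items whose
# moderate/severe report counts as "related symptoms" for detection.
# Categories mapping to no item (hyperlipasemia, nephritis) are laboratory
# findings with no instrument-visible symptom.
thyroiditis: [fatigue, headache, nausea_vomiting]
colitis_digestive: [diarrhea, nausea_vomiting, decreased_appetite]
hepatitis: [fatigue, nausea_vomiting]
skin_toxicity: [rash]
hypophysitis: [fatigue, headache, nausea_vomiting]
hyperlipasemia: []
rheumatological: [general_pain]
dry_syndrome: [blurred_vision]
myositis: [general_pain]
ophthalmological: [blurred_vision]
nephritis: []
mixed_connective_tissue: [general_pain]
interstitial_pneumonitis: [shortness_of_breath, fever]
other: []
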