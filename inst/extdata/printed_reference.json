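{
  "comment": "Published summary values from the source screening study, used by reproduce_paper() as the comparison surface. chi2/OR/ratio values are quoted to 2 decimal places; AUCs to 2 decimal places.",
  "n_controls": 895,
  "n_cases": 884,
  "age": {
    "control": { "mean": 12.67, "sd": 1.96 },
    "case": { "mean": 13.14, "sd": 1.87 }
  },
  "chi_square": {
    "gender": 146.84,
    "shoulder_height_diff": 333.96
  },
  "girls_to_boys_case_ratio": 1.84,
  "univariate_or": {
    "gender:girl": { "or": 3.26, "ci_low": 2.69, "ci_high": 3.96 },
    "scapular_tilt:right": { "or": 16.55 },
    "atr_thoracic:right_gt5": { "or": 14.41 },
    "atr_lumbar:left_gt5": { "or": 7.25 }
  },
  "auc": {
    "shoulder_height_diff": 0.70,
    "pelvic_tilt": 0.59,
    "atr_thoracic": 0.66,
    "atr_thoracolumbar": 0.54,
    "atr_lumbar": 0.67,
    "age": 0.57
  },
  "printed_aor": {
    "gender": 1.88,
    "age": 1.09,
    "shoulder_height_diff": [2.98, 4.17],
    "scapular_tilt": [2.23, 2.53],
    "lumbar_concave": [2.61, 2.67],
    "pelvic_tilt": [0.43, 1.83],
    "flat_back": 1.39,
    "thoracic_kyphosis": 1.48,
    "lumbar_kyphosis": 0.32,
    "atr_thoracic": [5.18, 10.06],
    "atr_thoracolumbar": [7.22, 4.67],
    "atr_lumbar": [6.97, 8.09]
  },
  "printed_auc_all": {
    "gender": 0.65,
    "age": 0.57,
    "shoulder_height_diff": 0.70,
    "scapular_tilt": 0.77,
    "lumbar_concave": 0.71,
    "pelvic_tilt": 0.59,
    "atr_thoracic": 0.66,
    "atr_thoracolumbar": 0.54,
    "atr_lumbar": 0.67
  }
}
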