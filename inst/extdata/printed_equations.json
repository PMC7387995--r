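{
  "comment": "Published AIS risk equations: logit(p) = intercept + sum(coef_i * X_i). X1 gender (boy=0, girl=1); X2 age in years; X3 shoulder-height difference, X4 scapular tilt, X5 lumbar concave, X6 pelvic tilt scored normal=0/left=1/right=2; X7 flat back, X8 thoracic kyphosis, X9 lumbar kyphosis scored normal=0/abnormal=1; X10-X12 thoracic/thoracolumbar/lumbar trunk-rotation angle scored ATR 0-5deg=0, left >5deg=1, right >5deg=2.",
  "equations": [
    {
      "id": 1,
      "scheme": "plain",
      "intercept": -7.124,
      "coefficients": {
        "X1": 0.705, "X2": 0.108, "X3": 0.705, "X4": 0.618,
        "X5": 0.790, "X6": -0.042, "X7": -0.965, "X8": 0.093,
        "X9": -2.235, "X10": 0.916, "X11": 1.406, "X12": 1.471
      }
    },
    {
      "id": 2,
      "scheme": "aor_weighted",
      "intercept": -3.648,
      "coefficients": {
        "X1": 0.367, "X2": 0.091, "X3": 0.316, "X4": 0.376,
        "X5": 0.435, "X6": 0.105, "X7": -0.984, "X8": -0.037,
        "X9": -2.122, "X10": 0.267, "X11": 0.275, "X12": 0.273
      }
    },
    {
      "id": 3,
      "scheme": "auc_weighted",
      "intercept": -3.787,
      "coefficients": {
        "X1": 0.448, "X2": 0.069, "X3": 0.650, "X4": 0.495,
        "X5": 0.756, "X6": -0.275, "X7": -0.827, "X8": -0.241,
        "X9": -1.955, "X10": 1.001, "X11": 1.420, "X12": 1.201
      }
    },
    {
      "id": 4,
      "scheme": "aor_auc_weighted",
      "intercept": -3.648,
      "coefficients": {
        "X1": 0.222, "X2": 0.058, "X3": 0.186, "X4": 0.213,
        "X5": 0.2546, "X6": 0.066, "X7": -0.984, "X8": -0.037,
        "X9": -2.122, "X10": 0.713, "X11": 0.166, "X12": 0.163
      }
    }
  ]
}
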