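{
  "version": "0.1.0",
  "population": {
    "n": 1000,
    "age_mean": 24.5,
    "age_sd": 5.2,
    "age_bounds": [18, 35],
    "sex_split": 0.5,
    "sport_props": {"running": 0.4, "jumping": 0.3, "cutting": 0.3},
    "train_mean": 8.5,
    "train_sd": 3.1,
    "component_means": [0.15, 0.08, 0.12, 0.10],
    "component_sds": [0.04, 0.03, 0.05, 0.04],
    "component_bounds": [[0.08, 0.25], [0.05, 0.20], [0.10, 0.28], [0.06, 0.22]],
    "correlation": [
      [1.00, 0.45, 0.35, 0.55],
      [0.45, 1.00, 0.25, 0.65],
      [0.35, 0.25, 1.00, 0.30],
      [0.55, 0.65, 0.30, 1.00]
    ],
    "noise_cv": 0.05,
    "seed": 42
  },
  "target_prevalence": 0.20,
  "target_auc": 0.89,
  "cv_folds": 5,
  "bootstrap_B": 2000,
  "hl_bins": 10,
  "sensitivity_delta": 0.05,
  "n_weight_configs": 100,
  "replicates": 1,
  "weights": {"fv": 0.35, "ta": 0.28, "ld": 0.22, "ba": 0.15},
  "seed": 42
}
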