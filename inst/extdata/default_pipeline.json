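{
  "analysis_rate": 500,
  "hp_cutoff": 0.5,
  "notch_freq": 50,
  "n_top_components": 10,
  "n_bins": 10,
  "per_band_k": 14,
  "split": 0.8,
  "n_boot": 100,
  "folds": 10,
  "repeats": 10,
  "csp_components": 4,
  "min_trials": 10,
  "seed": 1
}
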