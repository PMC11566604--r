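# Demo pipeline configuration: a short two-region free-behavior simulation
# run end to end. See ?run_pipeline for the full schema.
simulate:
  preset: custom
  duration_s: 240
  regions: [S1, M1]
  movement_bouts:
    rate_per_min: 2
    duration_mean_s: 5
    duration_sd_s: 1
    min_quiescence_s: 3
  seed: 21
preprocess:
  window_s: 60
connectivity:
  min_samples: 100
predict:
  lags_s: [0, 1, 2, 3]
  num_trees: 50
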