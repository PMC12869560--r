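# Example pipeline configuration: a small end-to-end run.
#   synthehr run --all --config example-config.yaml --out runs/demo
seed: 1
simulate:
  n_patients: 500
prepare:
  min_count: 50
  n_bands: 10
  fractions:
    train: 0.8
    validation: 0.1
    test: 0.1
train:
  n_layers: 2
  embedding_dim: 64
  n_heads: 4
  epochs: 10
  batch_size: 64
generate:
  n: 500
  # rules:
  #   - kind: forbid-co-occurrence
  #     antecedent: ["c:diagnosis:Z00.0"]
  #     consequent: ["c:diagnosis:R07.4"]
  # condition_labels: ["l:diabetes"]
evaluate:
  max_lag: 30
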