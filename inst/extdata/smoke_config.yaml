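# Small configuration for quick end-to-end runs (coarse mesh, few beats,
# short trainings). Any field omitted here falls back to default_config().
geometry:
  edge: 8.0
dataset:
  n_train: 400
  n_test: 60
  augmentation: 3
network:
  conv1: 8
  conv2: 16
  fc: 64
  epochs_classification: 8
  epochs_regression: 10
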