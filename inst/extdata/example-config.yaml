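# Example meta-training configuration for `metaplast meta-train`.
network:
  layer_sizes: [64, 32, 24, 16, 8]
  beta: 10
  feedback_mode: FA       # FA = fixed random feedback, BP = backprop
rule:
  name: eHebb             # FA_baseline | eHebb | Oja | bio | pool
  # or explicit terms:  terms: [0, 2]  /  init: [0.001, 0]
task:
  type: synthetic         # synthetic | idx (then: images:, labels:)
  class_pool_size: 20
  input_dim: 64
  noise_scale: 0.2
  seed: 11
meta:
  episodes: 100
  M: 5                    # classes per task
  K: 10                   # training items per class (M*K online steps)
  Q: 4                    # query items per class
  meta_learning_rate: 0.001
  l1_lambda: 0
  trial_seed: 1
trials: 1                 # >1 switches to multi-trial orchestration
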