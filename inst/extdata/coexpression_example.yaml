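study: coexpression
seed: 1
lambda: 50
n_draws: 1000
regulators:
  constant:
    family: constant
    value: 1
  low_dispersion:
    family: gamma
    shape: 50
    scale: 0.02
  high_dispersion:
    family: gamma
    shape: 2
    scale: 0.5
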