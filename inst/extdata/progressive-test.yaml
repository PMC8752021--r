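experiment: progressive-test
seed: 1
output_dir: "."
learning:
  strategy: gradient
  learning_rate: 0.2
objective:
  testbed: replicator
  extinction_fallback: 5
  stages:
    - {reference_step: 3000, rounds: 15}
    - {reference_step: 6000, rounds: 15}
    - {reference_step: 12000, rounds: 15}
    - {reference_step: 30000, rounds: 15}
world:
  lattice_side: 30
parameters:
  - {name: alpha_A, kind: positive-real, initial: 0.2}
  - {name: beta_A, kind: positive-real, initial: 2}
  - {name: gamma_A, kind: positive-real, initial: 200}
  - {name: alpha_B, kind: positive-real, initial: 0.2}
  - {name: beta_B, kind: positive-real, initial: 2}
  - {name: gamma_B, kind: positive-real, initial: 200}
  - {name: beta_C, kind: positive-real, initial: 1}
  - {name: gamma_C, kind: positive-real, initial: 5}
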