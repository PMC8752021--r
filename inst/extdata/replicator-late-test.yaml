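experiment: replicator-late-test
seed: 1
output_dir: "."
learning:
  strategy: gradient
  learning_rate: 0.2
  rounds: 30
objective:
  testbed: replicator
  reference_step: 30000
  extinction_fallback: 5
world:
  lattice_side: 30
  initial_occupancy: 0.5
  initial_length: 5
  decay_prob: 0.07
  dispersal_prob: 0.01
  base_error: 0.05
  indel_fraction: 0.2
  claim_scale: 0.2
  copy_cost_scale: 25
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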