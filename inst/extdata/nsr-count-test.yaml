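experiment: nsr-count-test
seed: 1
output_dir: "."
learning:
  strategy: gradient
  learning_rate: 0.5
  rounds: 30
  step_form: additive
  zero_change_direction: up
  replicates_per_evaluation: 1
  direction: ascent
objective:
  testbed: nsr
  readout: nsr_count
  reference_step: 5000
  inoculations:
    - species: nsr
      copies: 100
      step: 300
world:
  grid_side: 10
  total_material: 3000
  duplex_separation: 0.5
  knockout: false
parameters:
  - {name: PNF, kind: probability, initial: 0.004}
  - {name: PNFR, kind: probability, initial: 0.02}
  - {name: PND, kind: probability, initial: 0.001}
  - {name: PRL, kind: probability, initial: 2.0e-5}
  - {name: PBB, kind: probability, initial: 1.0e-5}
  - {name: PAT, kind: probability, initial: 0.5}
  - {name: PFP, kind: probability, initial: 0.1}
  - {name: PMV, kind: probability, initial: 0.001}
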