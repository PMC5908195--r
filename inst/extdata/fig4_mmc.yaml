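cascade:
  n_levels: 3.0
  n_membrane: 2.0
  alpha:
  - 1.0
  - 1.0
  - 1.0
  beta:
  - 0.5
  - 0.5
  - 0.5
  gamma: 0.0
  epsilon: 0.0
geometry:
  kind: sphere3d
  r_cell: 6.0
  r_nuc: 2.0
transport:
  d_cyt: 3.0
  d_mem: 0.03
signal:
  kind: exp_decay
  amplitude: 100.0
  decay_rate: 1.0
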