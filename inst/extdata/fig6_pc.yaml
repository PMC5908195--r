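cascade:
  n_levels: 3.0
  n_membrane: 0.0
  alpha:
  - 0.125
  - 0.125
  - 0.125
  beta:
  - 0.125
  - 0.125
  - 0.125
  gamma: 0.0
  epsilon: 0.0
geometry:
  kind: disc2d
  r_cell: 2.0
  r_nuc: 1.0
transport:
  d_cyt: 1.0
  d_mem: 0.01
signal:
  kind: constant
  amplitude: 100.0
feedback:
  km: 100.0
  hill_p: 10.0
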