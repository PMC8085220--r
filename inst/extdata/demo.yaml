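# Small demonstration configuration: a complete simulate -> train ->
# select -> reconstruct -> assess run in well under a minute. Every
# omitted key keeps its package default.
simulate:
  n_events: 2500
  n_train: 2500
selector:
  epochs: 8
  patience: 4
recon:
  nx: 21
  ny: 21
  nz: 1
  voxel: 3
  energy_min: 3.5
  energy_max: 5.5
  energy_step: 0.1
  iterations: 6
  n_rays: 45
  sensitivity: uniform
  max_events: 1200
assess:
  energy_window: [4.3, 4.5]
seed: 7
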