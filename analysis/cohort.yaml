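# Desk-scale study conditions for the synthetic cohort workflow.
seed: 1
atlas:
  n_areas: 40
  n_networks: 8
  n_lobes: 4
  min_separation: 6
  sigma_range: [1.8, 2.6]
cohort:
  n_per_class: 30
  grid_shape: [32, 32, 32]
  effect_size: 30
training:
  k: 4
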