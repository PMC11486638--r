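# Example run configuration for the cyclemorph CLI.
seed: 1
phantom:
  grid_shape: [32, 32, 32]
  voxel_size_mm: 1.5
  n_structures: 8
  atrophy_per_year: 0.004
effect:
  n_roi: 2
  radius_mm: 7
  reduction_fraction: 0.25
cohort:
  n_per_group: 30
model:
  base_channels: 8
  disc_blocks: 4
train:
  epochs: 12
stats:
  p_voxel: 0.001
  min_cluster_size: 10
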