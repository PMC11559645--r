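dimensionality: 2.0
roi:
  origin:
  - 0.0
  - 0.0
  extent:
  - 17320.0
  - 17320.0
margin:
- 900.0
- 900.0
row_spacing: 1850.0
row_jitter_sd: 60.0
off_row_fraction: 0.0
within_row_gap:
  mean: 690.624901351082485
  sd: 130.0
  min: 300.0
cluster_deletion_prob: 0.0
locs_per_cluster:
  meanlog: -2.07381629497805
  sdlog: 2.9
  min: 10.0
  max: 1500.0
small_cluster_fraction: 0.0
cluster_radius:
  mean: 33.232329994536784
  sd: 10.0
  min: 15.0
  max: 350.0
  n_ref: 30.0
axial_flattening: 0.6
loc_precision_sd:
  lateral: 20.0
  axial: 50.0
partner_mean_per_cluster: 16.0
partner_scatter_sd: 90.0
planted_empty_prob: 0.07
empty_exclusion: yes
partner_exclusion_radius: 240.0
partner_background_density: 6.0e-05
reference_background_density: 3.8e-05
qc_stress_fraction: 0.0
seed: 1
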