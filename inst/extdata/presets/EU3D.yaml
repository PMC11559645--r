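dimensionality: 3.0
roi:
  origin:
  - 0.0
  - 0.0
  - 0.0
  extent:
  - 14142.0
  - 14142.0
  - 1500.0
margin:
- 900.0
- 900.0
- 150.0
row_spacing: 1850.0
row_jitter_sd: 40.0
off_row_fraction: 0.0
within_row_gap:
  mean: 323.6138104056065
  sd: 120.0
  min: 250.0
cluster_deletion_prob: 0.0
locs_per_cluster:
  meanlog: 2.79428978135436
  sdlog: 1.1
  min: 10.0
  max: 1000.0
small_cluster_fraction: 0.313123014616016
cluster_radius:
  mean: 112.400883439305517
  sd: 20.0
  min: 30.0
  max: 350.0
  n_ref: 30.0
axial_flattening: 0.6
loc_precision_sd:
  lateral: 20.0
  axial: 50.0
partner_mean_per_cluster: 7.0
partner_scatter_sd: 90.0
planted_empty_prob: 0.1
empty_exclusion: yes
partner_exclusion_radius: 240.0
partner_background_density: 7.0e-09
reference_background_density: 1.5e-08
qc_stress_fraction: 0.0
seed: 1
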