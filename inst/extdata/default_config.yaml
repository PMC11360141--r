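contact_energy:
- - 0.0
  - 0.0
  - 4.0
  - 4.0
- - 0.0
  - 0.0
  - 3.0
  - 3.0
- - 4.0
  - 3.0
  - 4.0
  - 4.0
- - 4.0
  - 3.0
  - 4.0
  - 4.0
lambda_volume: 2.0
v_target: 125.0
temperature: 16.0
lambda_tissue: 150.0
lambda_lamellipodia: 1200.0
lambda_follower_substrate: 30.0
zeta_lamellipodia: 0.08
zeta_substrate: 0.2
zeta_tissue: 0.0
chi_lamellipodia: 12.0
kappa: 6.0
link_target_length: 5.0
substrate_link_target_length: 3.0
max_reformed_neighbors: 4
mcs_per_sample: 200
seconds_per_mcs: 5.0
microns_per_voxel: 6.0
bias_toward: far
leader_rows: bottom
connectivity_constraint: yes
lamellipodia_blocked: no
reach_tolerance: 1.0
seed: 1
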