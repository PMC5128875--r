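schema_version: 1
bead_diameters:
  NH: 3.3
  CA: 3.7
  CO: 3.5
sc_diameters:
  A: 2.7
  C: 3.6
  D: 3.9
  E: 4.2
  F: 4.6
  G: 2.0
  H: 4.3
  I: 4.3
  K: 4.4
  L: 4.3
  M: 4.3
  'N': 3.8
  P: 3.8
  Q: 4.1
  R: 4.6
  S: 3.3
  T: 3.7
  V: 4.0
  W: 4.7
  'Y': 4.6
sc_ca_dist:
  A: 1.55
  C: 2.05
  D: 2.45
  E: 2.9
  F: 2.9
  G: 0.0
  H: 3.1
  I: 2.3
  K: 3.0
  L: 2.6
  M: 2.95
  'N': 2.45
  P: 1.85
  Q: 3.0
  R: 3.4
  S: 1.9
  T: 1.95
  V: 1.95
  W: 3.4
  'Y': 3.2
sc_nh_dist:
  A: 2.6527
  C: 3.1055
  D: 3.4771
  E: 3.9018
  F: 3.9018
  G: 1.46
  H: 4.0923
  I: 3.337
  K: 3.997
  L: 3.618
  M: 3.9494
  'N': 3.4771
  P: 2.9226
  Q: 3.997
  R: 4.3797
  S: 2.9681
  T: 3.0138
  V: 3.0138
  W: 4.3797
  'Y': 4.1879
sc_co_dist:
  A: 2.6965
  C: 3.1474
  D: 3.5177
  E: 3.9412
  F: 3.9412
  G: 1.51
  H: 4.1312
  I: 3.378
  K: 4.0361
  L: 3.6582
  M: 3.9886
  'N': 3.5177
  P: 2.9651
  Q: 4.0361
  R: 4.4179
  S: 3.0105
  T: 3.056
  V: 3.056
  W: 4.4179
  'Y': 4.2266
sc_alpha: 0.20944
bonds:
  nh_ca: 1.46
  ca_co: 1.51
  co_nh: 1.33
  nh_co: 2.45
  ca_nh: 2.41
  co_ca: 2.45
  ca_ca: 3.8
bond_delta: 0.025
sc_bond_delta: 0.01
squeeze_factor: 0.75
eps_hb: 1.0
hb_range: 4.5
hb_core: 3.4
hb_aux_min: 4.5
hb_min_seq_sep: 4
salt_bridge:
  res_a: 23
  aa_a: D
  res_b: 28
  aa_b: K
  factor: 2.0
parallel_preference: yes
parallel_threshold: 1.570796
mass: 1.0
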