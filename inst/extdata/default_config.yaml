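phantom:
  outer_radius: 52.0
  csf_thickness: 5.0
  csf_smoothing: 2.5
  cortical_thickness: 3.0
  n_folds: 5
  fold_amplitude: 8.0
  fold_gap: 2.0
  ventricle_semiaxes:
  - 14.0
  - 8.0
  hippocampus_center:
  - 0.0
  - -16.0
  hippocampus_radius: 14.0
  target_edge_length: 2.15
  seed: 1
  dimension: 2
  slab_layers: 2
materials:
  WM:
    lambda: 64.67
    mu: 2.0
    G_h: 0.0015
    G_c: 0.0035
    c_crit: 0.5
    d: 15.0
    alpha: 0.09
  GM:
    lambda: 32.33
    mu: 1.0
    G_h: 0.001
    G_c: 0.002
    c_crit: 0.5
    d: 15.0
    alpha: 0.09
  HIPPO:
    lambda: 32.33
    mu: 1.0
    G_h: 0.001
    G_c: 0.002
    c_crit: 0.5
    d: 15.0
    alpha: 0.09
  VENT:
    lambda: 29.77
    mu: 15.34
    G_h: .na.real
    G_c: .na.real
    c_crit: .na.real
    d: 0.0
    alpha: 0.09
  CSF:
    lambda: 7.22
    mu: 14.43
    G_h: .na.real
    G_c: .na.real
    c_crit: .na.real
    d: 0.0
    alpha: 0.09
spreading:
  c0_seed: 0.3
  seed_region: HIPPO
simulation:
  t_end: 40.0
  dt: 0.1
  modes:
  - healthy
  - ad
  newton_tol: 1.0e-08
  newton_max_iter: 50.0
  dirichlet: csf_outer
  output_every: 40.0
  beta: 50.0
  theta_floor: 0.5
  seed: 1
output:
  dir: results
  write_vtu: no
  write_msh: no
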