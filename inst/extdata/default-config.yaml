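cell:
  g_na: 14.838
  g_k1: 5.405
  g_to: 0.294
  g_kr: 0.096
  g_ks: 0.062
  g_cal: 0.000175
  g_bna: 0.00029
  g_bca: 0.000592
  g_pk: 0.0146
  g_pca: 0.825
  k_nak: 1.362
  k_naca: 1000.0
  cm: 0.185
  cell_type: M
hf:
  f_to: 0.36
  f_ks: 0.5
  f_k1: 0.75
  f_na: 0.6
  f_cal: 0.85
  f_naca: 1.65
sac:
  g_sac: 0.025
  v_rev: -20.0
  k: 1.0
  alpha: 3.0
  half_sl0: 0.97
sarcomere:
  tt: 70.0
  y1: 0.039
  z1: 0.03
  y2: 0.0087
  z2: 0.0052
  y3: 0.012
  z3: 0.0039
  y4: 0.027
  b: 1.2
  hc: 0.005
  a_f: 9.5
  l_a: 0.55
  l_opt: 1.05
  k_p: 0.0
  beta_p: 10.0
  l0: 0.97
geometry:
  n_rings: 20.0
  nodes_per_ring: 24.0
  base_radius: 29.8
  apex_base_length: 53.7
  half_sl0: 0.97
loading:
  preload: 0.0
  lambda: 1.0
  filling_pressure: 10.0
  r_valve: 25.0
  r_peripheral: 1500.0
  c_arterial: 1.0
  p_arterial0: 80.0
  r_filling: 1.0e+07
mechanics:
  k_active: 15000.0
  k_passive: 60.0
  beta_passive: 8.0
  kappa: 0.0005
  tau_delta: 120.0
stimulus:
  amplitude: 52.0
  onset: 0.0
  duration: 1.0
tissue_stimulus:
  amplitude: 7.704
  onset: 0.0
  duration: 6.0
  site: apex_ring
numerics:
  dt: 0.02
  stride: 1.0
  d_coeff: 1.4
  duration_cell: 1000.0
  duration_tissue: 700.0
  prepace_beats: 10.0
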