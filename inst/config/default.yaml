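seed: 1
scale: default
layout:
  n_rows: 16
  n_cols: 16
  isms:
  - K
  - Na
  - Ca
population:
  yield_p: 0.84
panel:
  v_gs_from: -0.6
  v_gs_to: 0.9
  v_gs_by: 0.01
  v_ds: 0.3
  noise_rel: 0.01
  c_ref: 0.001
  concentrations:
  - 1.0e-05
  - 1.0e-04
  - 1.0e-03
  - 1.0e-02
  - 1.0e-01
  hysteresis_V: 0.002
calibration:
  ism: Ca
  test_v_gs: 0.0
  true_conc: 0.01
redundancy:
  n_synthetic: 50000
  n_repeats: 1000
  sample_sizes:
  - 5
  - 25
  - 100
  - 215
ml:
  n_triplets: 200
  noise_frac: 0.05
  n_repeats: 5
  trees: 100
  depth: 20
  tasks:
  - ion_type
  - conc_K
  - conc_Na
  - conc_Ca
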