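# bundled synthetic demo run: small cohort, all stages
seed: 1
n_cases: 8
n_saccular: 4
phases: 20
period: 1
stages: [simulate, wss, vortex, morphology, radiomics, correlate]
wss:
  weighting: area
  rule: rectangle
vortex:
  criterion: Q
  threshold: 1
  min_cells: 5
  cyclic: true
  mesh_edge_factor: 0.28
radiomics:
  policy: fixed_bin_count
  n_bins: 16
  alpha: 0
  shift: 0
  image_shape: [12, 12, 8]
correlate:
  rho_threshold: 0.7
  alpha: 0.05
  mode: abs
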