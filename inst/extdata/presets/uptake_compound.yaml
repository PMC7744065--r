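name: uptake_compound
model: transporter
description: >
  Communal-transporter competition with the glucose binding coefficient
  inside the titration window (K_gluc = 1e7 against 1e5..1e10): below
  K_gluc the transporters are not glucose-saturated and the circuit acts
  as a galactose threshold sensor, above it the response is ratiometric --
  a compound signal-integration mode.
regime: compound
expected_pattern: compound
expected_segment_classes: [galactose_threshold, ratio]
grid:
  gal_min: 1.0e+5
  gal_max: 1.0e+10
  gluc_min: 1.0e+5
  gluc_max: 1.0e+10
  n_per_axis: 30
params:
  K_gal: 1.0e+7
  K_gluc: 1.0e+7
  k_trans: 1.0
  gamma: 1.0
  T_total: 100.0
  n_gal: 1.0
  n_gluc: 1.0
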