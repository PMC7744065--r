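name: uptake_full_ratio
model: transporter
description: >
  Communal-transporter competition with the glucose binding coefficient far
  below the whole glucose titration range (K_gluc = 1e5 against a 1e7..1e13
  window), so the transporter pool is glucose-saturated everywhere and the
  decision front is a full-range ratiometric diagonal.
regime: full_range_ratio
expected_pattern: ratio
grid:
  gal_min: 1.0e+7
  gal_max: 1.0e+13
  gluc_min: 1.0e+7
  gluc_max: 1.0e+13
  n_per_axis: 30
params:
  K_gal: 1.0e+5
  K_gluc: 1.0e+5
  k_trans: 1.0
  gamma: 1.0
  T_total: 100.0
  n_gal: 1.0
  n_gluc: 1.0
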