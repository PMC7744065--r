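name: txn_activator_saturated
model: transcription
description: >
  Deliberate violation of gal_in << K_G: the activator's sensor saturates
  inside the titration window (K_G = 0.1), so the circuit is ratiometric
  at low sugar levels but responds only to glucose at high levels
  (glucose threshold sensing at high carbon source concentrations).
regime: compound
expected_pattern: compound
expected_segment_classes: [ratio, glucose_threshold]
satisfies: [glucin_gg_KMoverPhiR, glucin_ll_KM]
violates: [galin_ll_KG]
grid:
  gal_min: 1.0e-4
  gal_max: 1.0e+2
  gluc_min: 1.0e-4
  gluc_max: 1.0e+2
  n_per_axis: 30
params:
  K_G: 1.0e-1
  K_M: 1.0e+5
  K_A: 1.0
  K_R: 1.0
  phiA: 1.0e+6
  phiR: 1.0e+12
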