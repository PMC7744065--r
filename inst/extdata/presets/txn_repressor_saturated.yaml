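name: txn_repressor_saturated
model: transcription
description: >
  Deliberate violation of gluc_in << K_M: the repressor's sensor saturates
  inside the window (K_M = 0.1), so additional glucose above K_M changes
  nothing and the circuit turns into a galactose threshold sensor at high
  concentrations; ratio sensing holds at low concentrations.
regime: compound
expected_pattern: compound
expected_segment_classes: [ratio, galactose_threshold]
satisfies: [galin_ll_KG, glucin_gg_KMoverPhiR]
violates: [glucin_ll_KM]
grid:
  gal_min: 1.0e-4
  gal_max: 1.0e+2
  gluc_min: 1.0e-4
  gluc_max: 1.0e+2
  n_per_axis: 30
params:
  K_G: 1.0e+6
  K_M: 1.0e-1
  K_A: 1.0
  K_R: 1.0
  phiA: 1.0e+11
  phiR: 1.0e+6
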