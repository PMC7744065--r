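name: txn_weak_repression
model: transcription
description: >
  Deliberate violation of gluc_in >> K_M/phiR: the repression capacity is
  small (phiR = 1e5, putting K_M/phiR = 1 inside the window), so at low
  glucose the repressor never engages the CRE and the circuit is a pure
  galactose threshold sensor; ratio sensing only appears at high
  concentrations.
regime: compound
expected_pattern: compound
expected_segment_classes: [galactose_threshold, ratio]
satisfies: [galin_ll_KG, glucin_ll_KM]
violates: [glucin_gg_KMoverPhiR]
grid:
  gal_min: 1.0e-4
  gal_max: 1.0e+2
  gluc_min: 1.0e-4
  gluc_max: 1.0e+2
  n_per_axis: 30
params:
  K_G: 1.0e+6
  K_M: 1.0e+5
  K_A: 1.0
  K_R: 1.0
  phiA: 1.0e+8
  phiR: 1.0e+5
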