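name: txn_full_ratio
model: transcription
description: >
  Basic transcriptional competition unit inside its ratio-sensing regime:
  over the whole 1e-4..1e2 intracellular window, gal_in << K_G and
  K_M/phiR << gluc_in << K_M each hold with at least 100x margin, so the
  half-maximal decision front is a slope-1 diagonal.
regime: ratio
expected_pattern: ratio
satisfies: [galin_ll_KG, glucin_gg_KMoverPhiR, glucin_ll_KM]
violates: []
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
  phiA: 1.0e+13
  phiR: 1.0e+12
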