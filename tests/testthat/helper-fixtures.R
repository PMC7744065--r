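# shared fixtures: random valid parameter draws and small grids

log_unif <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))

rand_transporter_params <- function() {
  transporter_params(kf_gal = log_unif(1e-2, 1e2), kr_gal = log_unif(1e-2, 1e2),
                     kf_gluc = log_unif(1e-2, 1e2), kr_gluc = log_unif(1e-2, 1e2),
                     k_trans = log_unif(1e-1, 1e1), gamma = log_unif(1e-1, 1e1),
                     T_total = log_unif(1, 1e3))
}

rand_transcription_params <- function() {
  transcription_params(K_G = log_unif(1e-1, 1e3), K_M = log_unif(1e-1, 1e3),
                       K_A = log_unif(1e-1, 1e1), K_R = log_unif(1e-1, 1e1),
                       Activator_total = log_unif(1, 1e4),
                       Repressor_total = log_unif(1, 1e4))
}

# cooperative uptake parameters whose half-maximal front passes through
# 10^m on both axes of a gluc-saturated window
coop_transporter_params <- function(n_gal, n_gluc, m = 9, lKgluc = 5,
                                    K_gal_factor = 1) {
  lKgal <- m + (n_gluc / n_gal) * (lKgluc - m)
  transporter_params_from_K(K_gal_factor * 10^lKgal, 10^lKgluc,
                            n_gal = n_gal, n_gluc = n_gluc)
}

ratio_txn_params <- function() {
  transcription_params(K_G = 1e6, K_M = 1e5, phiA = 1e13, phiR = 1e12)
}

default_grid <- function(n = 30) make_log_grid(n_per_axis = n)

# classes of contour segments at least 3 points long
segment_classes_of <- function(cls) ratiosense:::segment_classes(cls)
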