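base_p <- motif_base_params()

test_that("generalized occupancy reduces to the basic unit and has the right limits", {
  p <- transcription_params(K_G = 1, K_M = 1, K_A = 3, K_R = 1,
                            phiA = 1, phiR = 1)
  # saturating activating signal, no repressor, A_total = K_A: balance at 1/2
  expect_equal(generalized_active_fraction(1e9, 1, p$K_A, 0, p), 0.5,
               tolerance = 1e-6)
  expect_equal(generalized_active_fraction(0, 1, 10, 10, p), 0)
  # constant pools reproduce active_fraction exactly
  q <- ratio_txn_params()
  gal <- 10^runif(20, -4, 2); gluc <- 10^runif(20, -4, 2)
  expect_equal(generalized_active_fraction(gal, gluc, q$Activator_total,
                                           q$Repressor_total, q),
               active_fraction(gal, gluc, q))
})

test_that("pool fixed points match closed forms and asymptotics", {
  cfg0 <- motif_config("none", "none", base = base_p, A0 = 1e13, R0 = 1e12)
  tot <- solve_effective_totals(cfg0, c(0.1, 5), c(0.1, 5))
  expect_equal(tot$A_total, c(1e13, 1e13))
  expect_equal(tot$R_total, c(1e12, 1e12))

  # negative auto-regulation: quadratic fixed point, sqrt asymptote
  negA <- motif_config("negative_auto", "none", base = base_p,
                       A0 = 1e16, R0 = 1e12, Kx = 1e2)
  S_A <- 10^seq(-3, 1, length.out = 9)
  A <- solve_effective_totals(negA, S_A, 1)$A_total
  a <- S_A / (base_p$K_G + S_A)
  expect_equal(A, 1e16 / (1 + a * A / 1e2), tolerance = 1e-12)  # fixed point
  expect_equal(A, sqrt(1e16 * 1e2 / a), tolerance = 2e-2)       # deep regime
  expect_true(all(diff(A) < 0))

  # positive auto-regulation: shifted-pool branch A0 - Kx/a above onset
  posA <- motif_config("positive_auto", "none", base = base_p,
                       A0 = 1e13, R0 = 1e12, Kx = 1e4)
  A1 <- solve_effective_totals(posA, 0.1, 1)$A_total
  expect_equal(A1, 1e13 - 1e4 * (base_p$K_G + 0.1) / 0.1, tolerance = 1e-12)
  expect_equal(solve_effective_totals(posA, 1e-8, 1)$A_total, 0)  # extinct
})

test_that("the direct solver agrees with damped fixed-point iteration", {
  set.seed(21)
  presets <- motif_census_presets(default_grid(12))
  picks <- c("negative_auto.none", "positive_auto.negative_auto",
             "coherent_ffl_edge.incoherent_ffl_edge",
             "incoherent_ffl_edge.coherent_ffl_edge",
             "coherent_ffl_edge.coherent_ffl_edge",
             "incoherent_ffl_edge.incoherent_ffl_edge")
  S_A <- 10^runif(6, -3, 1); S_R <- 10^runif(6, -3, 1)
  for (nm in picks) {
    cfg <- presets[[nm]]
    direct <- solve_effective_totals(cfg, S_A, S_R)
    iter <- ratiosense:::solve_totals_iterative(cfg, S_A, S_R, tol = 1e-13)
    expect_equal(direct$A_total, iter$A_total, tolerance = 1e-6, label = nm)
    expect_equal(direct$R_total, iter$R_total, tolerance = 1e-6, label = nm)
  }
})

test_that("saturated-off regulatory edges degenerate to the basic unit", {
  g <- default_grid(10)
  basic <- simulate_motif_grid(
    g, motif_config("none", "none", base = base_p, A0 = 1e13, R0 = 1e12))
  # inhibitory forms switch off as K -> Inf
  for (st in c("negative_auto", "coherent_ffl_edge")) {
    off_A <- simulate_motif_grid(g, motif_config(st, "none", base = base_p,
                                                 A0 = 1e13, R0 = 1e12, Kx = 1e30))
    expect_equal(off_A$values, basic$values, tolerance = 1e-6, label = st)
  }
  # promoting forms saturate on as K -> 0
  for (st in c("positive_auto", "incoherent_ffl_edge")) {
    on_A <- simulate_motif_grid(g, motif_config(st, "none", base = base_p,
                                                A0 = 1e13, R0 = 1e12, Kx = 1e-30))
    expect_equal(on_A$values, basic$values, tolerance = 1e-6, label = st)
  }
})

test_that("analytic fronts carry the predicted slope multipliers", {
  mk <- function(a, r) motif_config(a, r, base = base_p, A0 = 1e13, R0 = 1e12,
                                    Kx = 1, Ky = 1)
  expect_equal(motif_front_analytic(mk("negative_auto", "none"))$slope, 0.5)
  expect_equal(motif_front_analytic(mk("coherent_ffl_edge", "none"))$slope, 0.5)
  expect_equal(motif_front_analytic(mk("none", "negative_auto"))$slope, 2)
  expect_equal(motif_front_analytic(mk("none", "coherent_ffl_edge"))$slope, 2)
  for (st in c("positive_auto", "incoherent_ffl_edge")) {
    expect_equal(motif_front_analytic(mk(st, "none"))$slope, 1)
    expect_equal(motif_front_analytic(mk("none", st))$slope, 1)
  }
  expect_equal(motif_front_analytic(mk("none", "none"))$slope_multiplier, 1)
  expect_error(motif_front_analytic(mk("negative_auto", "negative_auto")),
               "both nodes")
})

test_that("fitted fronts of the eight single-motif circuits match the analytic lines", {
  grid <- default_grid()
  presets <- motif_census_presets(grid)
  singles <- c("negative_auto.none", "positive_auto.none",
               "coherent_ffl_edge.none", "incoherent_ffl_edge.none",
               "none.negative_auto", "none.positive_auto",
               "none.coherent_ffl_edge", "none.incoherent_ffl_edge")
  for (nm in singles) {
    cfg <- presets[[nm]]
    an <- motif_front_analytic(cfg, 0.5)
    fit <- fit_front(extract_decision_front(simulate_motif_grid(grid, cfg), 0.5))
    expect_lt(abs(fit$slope - an$slope) / an$slope, 0.05)
    expect_lt(abs(fit$intercept - an$intercept), 0.1)
  }
})

test_that("shifted-argument fronts straighten in the shifted coordinate", {
  grid <- default_grid()
  cfg <- motif_config("positive_auto", "none", base = base_p,
                      A0 = 1e13, R0 = 1e12, Kx = 1e4)
  an <- motif_front_analytic(cfg, 0.5)
  x0 <- an$shift$value
  fr <- extract_decision_front(simulate_motif_grid(grid, cfg), 0.5)
  sub <- fr[10^fr$log_gal > 2 * x0, ]
  shifted <- ratiosense:::ls_line(log10(10^sub$log_gal - x0), sub$log_gluc)
  plain <- ratiosense:::ls_line(sub$log_gal, sub$log_gluc)
  expect_equal(shifted$slope, 1, tolerance = 0.02)
  expect_lt(shifted$residual, plain$residual / 3)
})

test_that("the regulatory-state space enumerates to 25 unique configurations", {
  cfgs <- enumerate_configurations()
  expect_equal(nrow(cfgs), 25L)
  expect_equal(nrow(unique(cfgs)), 25L)
  expect_equal(sum(cfgs$activator_state == "none" &
                     cfgs$repressor_state == "none"), 1L)
  expect_equal(sum(cfgs$activator_state == "none"), 5L)
})

test_that("the census partitions the 25 configurations into 6 halving, 13 neutral, 6 doubling", {
  grid <- default_grid()
  presets <- motif_census_presets(grid)
  census <- census_slope_multipliers(presets, grid)
  expect_equal(nrow(census), 25L)
  expect_false(any(census$ambiguous))
  counts <- attr(census, "counts")
  expect_equal(unname(counts), c(6L, 13L, 6L))
  halving_states <- c("negative_auto", "coherent_ffl_edge")
  halved <- census$multiplier == 0.5
  doubled <- census$multiplier == 2
  # halving: negative auto-regulation of the activator and/or an inhibitory
  # edge from the repressor to the activator, with a neutral repressor node
  expect_true(all(census$activator_state[halved] %in% halving_states))
  expect_true(all(!census$repressor_state[halved] %in% halving_states))
  # doubling: the mirror statement on the repressor node
  expect_true(all(census$repressor_state[doubled] %in% halving_states))
  expect_true(all(!census$activator_state[doubled] %in% halving_states))
  # opposing motifs on the two nodes cancel back to slope 1
  both <- census$activator_state %in% halving_states &
    census$repressor_state %in% halving_states
  expect_true(all(census$multiplier[both] == 1))
})

test_that("the census partition is stable under twofold parameter perturbation", {
  grid <- default_grid()
  presets <- motif_census_presets(grid)
  pert <- lapply(presets, function(cfg)
    motif_config(cfg$activator_state, cfg$repressor_state, base = cfg$base,
                 A0 = 2 * cfg$A0, R0 = 2 * cfg$R0,
                 Kx = if (is.na(cfg$Kx)) NA else 2 * cfg$Kx,
                 Ky = if (is.na(cfg$Ky)) NA else 2 * cfg$Ky))
  census <- census_slope_multipliers(pert, grid)
  expect_false(any(census$ambiguous))
  expect_equal(unname(attr(census, "counts")), c(6L, 13L, 6L))
})
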