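test_that("quasi-equilibrium regulator levels follow hyperbolic saturation", {
  p <- transcription_params(K_G = 10, K_M = 3, Activator_total = 40,
                            Repressor_total = 8)
  expect_equal(activator_equilibrium(0, p), 0)
  expect_equal(activator_equilibrium(p$K_G, p), p$Activator_total / 2)
  expect_equal(activator_equilibrium(30, p), 30)  # 3 K_G -> 3/4 of 40
  expect_equal(repressor_equilibrium(0, p), 0)
  expect_equal(repressor_equilibrium(p$K_M, p), p$Repressor_total / 2)
  expect_equal(repressor_equilibrium(1, p), 2)    # K_M/3 -> 1/4 of 8
})

test_that("active fraction has the closed-form limits", {
  p <- transcription_params(K_G = 1, K_M = 1, phiA = 1, phiR = 5)
  expect_equal(active_fraction(0, 3, p), 0)
  # no repressor, saturating galactose, phiA = 1: occupancy balance gives 1/2
  expect_equal(active_fraction(1e9, 0, p), 0.5, tolerance = 1e-6)
  f <- active_fraction(10^runif(50, -3, 3), 10^runif(50, -3, 3), p)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("closed-form occupancy matches the dynamic mass-action oracle", {
  set.seed(4242)
  for (i in 1:20) {
    p <- rand_transcription_params()
    gal <- log_unif(1e-2, 1e2) * p$K_G
    gluc <- log_unif(1e-2, 1e2) * p$K_M
    o <- suppressWarnings(integrate_transcription(gal, gluc, p))
    expect_equal(o$active_fraction, active_fraction(gal, gluc, p),
                 tolerance = 1e-6)
    # GAL1 copy conservation at steady state
    expect_lte(unname(o$state["GAL1_active"] + o$state["GAL1_repressed"]),
               p$GAL1_total + 1e-9)
  }
})

test_that("active fraction is monotone in both intracellular sugars", {
  p <- ratio_txn_params()
  g <- default_grid(15)
  surf <- simulate_transcription_grid(g, p, normalize = FALSE)
  expect_true(all(apply(surf$values, 2, diff) >= 0))
  expect_true(all(apply(surf$values, 1, diff) <= 0))
})

test_that("analytic transcription front has slope 1 and capacity-controlled intercept", {
  p_sym <- transcription_params(K_G = 7, K_M = 7, phiA = 100, phiR = 100)
  f <- transcription_front_analytic(p_sym, 0.5)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  p <- ratio_txn_params()
  expect_equal(transcription_front_analytic(p)$slope, 1)
  # tenfold repression capacity shifts the front down one decade
  p10 <- transcription_params(K_G = p$K_G, K_M = p$K_M,
                              phiA = p$phiA, phiR = 10 * p$phiR)
  expect_equal(transcription_front_analytic(p10)$intercept,
               transcription_front_analytic(p)$intercept - 1)
  expect_error(transcription_front_analytic(p, 0), "between 0 and 1")
})

test_that("regime report flags each inequality with its margin", {
  p <- ratio_txn_params()
  g <- default_grid()
  rep <- check_ratio_regime(p, g$gal, g$gluc, factor = 100)
  expect_true(rep$galin_ll_KG && rep$glucin_gg_KMoverPhiR && rep$glucin_ll_KM)
  expect_equal(rep$predicted_pattern, "full-range ratio-sensing")
  # gal range touching K_G flips the first flag
  rep2 <- check_ratio_regime(p, c(1e-4, p$K_G / 10), g$gluc, factor = 100)
  expect_false(rep2$galin_ll_KG)
  expect_match(rep2$predicted_pattern, "glucose threshold sensing at high")
  # glucose range crossing K_M flips the saturation flag
  rep3 <- check_ratio_regime(p, g$gal, c(1e-4, 10 * p$K_M), factor = 100)
  expect_false(rep3$glucin_ll_KM)
  expect_match(rep3$predicted_pattern, "galactose threshold sensing at high")
  # glucose range dipping below K_M/phiR flips the repression-capacity flag
  p_weak <- transcription_params(K_G = 1e6, K_M = 1e5, phiA = 1e8, phiR = 1e5)
  rep4 <- check_ratio_regime(p_weak, g$gal, g$gluc, factor = 100)
  expect_false(rep4$glucin_gg_KMoverPhiR)
  expect_match(rep4$predicted_pattern, "galactose threshold sensing at low")
})

test_that("regime-satisfying and regime-violating presets reproduce their patterns", {
  ratio <- load_preset("txn_full_ratio")
  cls <- classify_pattern(simulate_transcription_grid(ratio$grid, ratio$params))
  expect_equal(cls$pattern, "ratio")
  fit <- fit_front(cls$front)
  expect_lt(abs(fit$slope - 1), 0.05)

  for (nm in c("txn_activator_saturated", "txn_weak_repression",
               "txn_repressor_saturated")) {
    e <- load_preset(nm)
    cls <- classify_pattern(simulate_transcription_grid(e$grid, e$params))
    expect_equal(cls$pattern, "compound", label = nm)
    expect_setequal(segment_classes_of(cls), e$expected_segment_classes)
  }
})
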