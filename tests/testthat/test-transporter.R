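test_that("mass-action derivatives match hand evaluation and conserve transporters", {
  p <- transporter_params(kf_gal = 1, kr_gal = 1, kf_gluc = 1, kr_gluc = 1,
                          k_trans = 1, gamma = 1, T_total = 100)
  # no ligand, empty cell: nothing moves
  d0 <- transporter_rhs(transporter_state(T_free = 100), 0, 0, p)
  expect_equal(unname(d0), rep(0, 5))
  # association flux from a fully free pool: kf * gal_ex * T_free = 100
  d1 <- transporter_rhs(transporter_state(T_free = 100), 1, 0, p)
  expect_equal(unname(d1["galT"]), 100)
  # transporter-pool derivatives always sum to zero
  set.seed(1)
  for (i in 1:20) {
    s <- transporter_state(runif(1, 0, 5), runif(1, 0, 5),
                           runif(1, 0, 40), runif(1, 0, 40), runif(1, 0, 40))
    d <- transporter_rhs(s, runif(1, 0, 10), runif(1, 0, 10), p)
    expect_equal(unname(d["galT"] + d["glucT"] + d["T_free"]), 0)
  }
  expect_error(transporter_rhs(transporter_state(T_free = 1), -1, 0, p),
               "non-negative")
})

test_that("closed-form steady state has the right limits", {
  p <- transporter_params_from_K(50, 200, T_total = 100)
  expect_equal(transporter_steady_state(p$K_gal, 0, p)$gal_in, p$psi / 2)
  expect_equal(transporter_steady_state(1e12, 777, p)$gal_in, p$psi,
               tolerance = 1e-6)
  expect_equal(transporter_steady_state(0, 10, p)$gal_in, 0)
  # gal_in / gluc_in equals the K-scaled external concentration ratio
  ss <- transporter_steady_state(30, 70, p)
  expect_equal(ss$gal_in / ss$gluc_in, (30 / p$K_gal) / (70 / p$K_gluc))
})

test_that("closed form agrees with long-time integration of the mass-action system", {
  set.seed(42)
  for (i in 1:20) {
    p <- rand_transporter_params()
    gal <- log_unif(1e-2, 1e2) * p$K_gal
    gluc <- log_unif(1e-2, 1e2) * p$K_gluc
    o <- suppressWarnings(integrate_transporter(gal, gluc, p))
    cf <- transporter_steady_state(gal, gluc, p)
    expect_equal(o$gal_in, cf$gal_in, tolerance = 1e-6)
    expect_equal(o$gluc_in, cf$gluc_in, tolerance = 1e-6)
    # transporter pools conserved at steady state
    expect_equal(unname(sum(o$state[c("galT", "glucT", "T_free")])),
                 p$T_total, tolerance = 1e-8)
  }
})

test_that("intracellular galactose is monotone in both external sugars", {
  p <- transporter_params_from_K(1e5, 1e5)
  g <- make_log_grid(1e3, 1e8, 1e3, 1e8, 15)
  surf <- simulate_transporter_grid(g, p, normalize = FALSE)
  expect_true(all(apply(surf$values, 2, diff) >= 0))  # increasing in gal
  expect_true(all(apply(surf$values, 1, diff) <= 0))  # decreasing in gluc
})

test_that("analytic uptake front has slope n_gal/n_gluc with the level constant", {
  p <- transporter_params_from_K(1, 1)
  f <- transporter_front_analytic(p, 0.5)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)  # log10(1/0.5 - 1) = 0 and K_gal = K_gluc
  expect_equal(transporter_front_analytic(
    transporter_params_from_K(1, 1, n_gal = 20, n_gluc = 1))$slope, 20)
  expect_equal(transporter_front_analytic(
    transporter_params_from_K(1, 1, n_gal = 1, n_gluc = 20))$slope, 0.05)
  expect_error(transporter_front_analytic(p, 1.2), "between 0 and 1")
})

test_that("fitted front slope tracks the cooperativity ratio and K scaling shifts it", {
  grid <- make_log_grid(1e7, 1e11, 1e7, 1e11, 240)
  for (nn in list(c(20, 1), c(2, 1), c(1, 1), c(1, 2), c(1, 20))) {
    p <- coop_transporter_params(nn[1], nn[2])
    fr <- extract_decision_front(simulate_transporter_grid(grid, p), 0.5)
    fit <- fit_front(fr)
    target <- nn[1] / nn[2]
    expect_lt(abs(fit$slope - target) / target, 0.05)
    # doubling K_gal moves the front toward higher galactose by log10(2),
    # the horizontal shift the analytic front predicts, at unchanged slope
    p2 <- coop_transporter_params(nn[1], nn[2], K_gal_factor = 2)
    fr2 <- extract_decision_front(simulate_transporter_grid(grid, p2), 0.5)
    common <- intersect(fr$log_gluc, fr2$log_gluc)
    dx <- mean(fr2$log_gal[match(common, fr2$log_gluc)] -
                 fr$log_gal[match(common, fr$log_gluc)])
    expect_equal(dx, log10(2), tolerance = 1e-3)
    expect_lt(abs(fit_front(fr2)$slope - target) / target, 0.05)
  }
})

test_that("uptake presets reproduce the full-range and compound regimes", {
  full <- load_preset("uptake_full_ratio")
  expect_equal(full$params$K_gluc, 1e5)
  cls_full <- classify_pattern(simulate_transporter_grid(full$grid, full$params))
  expect_equal(cls_full$pattern, "ratio")
  comp <- load_preset("uptake_compound")
  expect_equal(comp$params$K_gluc, 1e7)
  cls_comp <- classify_pattern(simulate_transporter_grid(comp$grid, comp$params))
  expect_equal(cls_comp$pattern, "compound")
  expect_setequal(segment_classes_of(cls_comp), c("galactose_threshold", "ratio"))
})
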