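test_that("a sharp diagonal surface yields a unit-slope front", {
  g <- make_log_grid(1e-2, 1e2, 1e-2, 1e2, 20)
  v <- outer(log10(g$gal), log10(g$gluc),
             function(x, y) as.numeric(y < x))
  surf <- response_surface(g, v, normalized = TRUE)
  fit <- fit_front(extract_decision_front(surf, 0.5))
  expect_equal(fit$slope, 1, tolerance = 0.05)
})

test_that("fitting collinear points is exact and refitting a sampled line recovers it", {
  x <- seq(-3, 2, length.out = 12)
  fr <- data.frame(log_gal = x, log_gluc = 2 * x - 0.75)
  f <- fit_front(fr)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, -0.75)
  expect_equal(f$residual, 0)
  expect_false(f$vertical)
  # self-consistency for arbitrary line coefficients
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, -3, 3); b <- runif(1, -2, 2)
    f <- fit_front(data.frame(log_gal = x, log_gluc = a * x + b))
    expect_equal(f$slope, a, tolerance = 1e-10)
    expect_equal(f$intercept, b, tolerance = 1e-10)
  }
  expect_error(fit_front(fr[1:3, ]), "at least 4")
})

test_that("a galactose-only surface gives a vertical front flagged, not an infinite slope", {
  g <- make_log_grid(1e-2, 1e2, 1e-2, 1e2, 15)
  v <- matrix(rep(1 / (1 + (1 / g$gal)), 15), 15, 15)  # depends on gal only
  surf <- response_surface(g, v, normalized = TRUE)
  f <- fit_front(extract_decision_front(surf, 0.5))
  expect_true(f$vertical)
  expect_true(is.na(f$slope))
  cls <- classify_pattern(surf)
  expect_equal(cls$pattern, "galactose_threshold")
})

test_that("front points lie on the analytic transcription front", {
  p <- ratio_txn_params()
  surf <- simulate_transcription_grid(default_grid(), p)
  fr <- extract_decision_front(surf, 0.5)
  an <- transcription_front_analytic(p, 0.5)
  pred <- an$slope * fr$log_gal + an$intercept
  expect_lt(max(abs(fr$log_gluc - pred)), 0.05)
})

test_that("raising the level moves the front toward higher galactose", {
  p <- ratio_txn_params()
  surf <- simulate_transcription_grid(default_grid(), p)
  lo <- extract_decision_front(surf, 0.3)
  hi <- extract_decision_front(surf, 0.7)
  common <- intersect(lo$log_gluc, hi$log_gluc)
  expect_true(all(hi$log_gal[match(common, hi$log_gluc)] >
                    lo$log_gal[match(common, lo$log_gluc)]))
  expect_error(extract_decision_front(surf, 2), "inside the surface range")
})

test_that("local slopes are constant on straight fronts and noise-tolerant", {
  x <- seq(-3, 2, length.out = 30)
  fr <- data.frame(log_gal = x, log_gluc = 1.5 * x + 0.2)
  expect_equal(local_slopes(fr, 5), rep(1.5, 30))
  expect_error(local_slopes(fr, 2), ">= 3")
  set.seed(8)
  noisy <- within(fr, log_gluc <- log_gluc + rnorm(30, 0, 0.05))
  expect_lt(abs(mean(local_slopes(noisy, 7)) - 1.5) / 1.5, 0.1)
})

test_that("too-short fronts are reported unclassifiable", {
  g <- make_log_grid(1, 100, 1, 100, 8)
  v <- matrix(0.9, 8, 8); v[1, 8] <- 0.1  # level barely crossed anywhere
  cls <- classify_pattern(response_surface(g, v, normalized = TRUE), 0.5)
  expect_equal(cls$pattern, "unclassifiable")
})
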