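test_that("covariate factors follow the 1 + theta * covariate structure", {
  expect_equal(covariate_factor_continuous(0, 123), 1)
  expect_equal(covariate_factor_continuous(0.18, 4), 1.72)
  expect_equal(covariate_factor_continuous(130, 6), 781)
  expect_equal(covariate_factor_categorical(0.14, 0), 1)
  expect_equal(covariate_factor_categorical(0.14, 1), 1.14)
  expect_equal(covariate_factor_categorical(0.41, 1), 1.41)
  expect_error(covariate_factor_continuous(-0.5, 3), "non-positive")
  expect_error(covariate_factor_categorical(0.3, 2), "0/1")
})

test_that("placebo effect is piecewise linear with a kink at induction end", {
  expect_equal(placebo_effect(0, 56, 0.015, 0.001), 0)
  expect_equal(placebo_effect(56, 56, 0.015), -0.84)
  expect_equal(placebo_effect(156, 56, 0.015, 0.001), -0.94)
  # continuity at the boundary and linearity within phases
  t <- seq(0, 364, by = 1)
  p <- placebo_effect(t, 56, 0.015, 0.001)
  expect_equal(diff(p)[t[-1] <= 56], rep(-0.015, 56), ignore_attr = TRUE)
  expect_equal(diff(p)[t[-1] > 56], rep(-0.001, 308), ignore_attr = TRUE)
})

test_that("cumulative logits reproduce hand-computed cut-point arithmetic", {
  # uncentered baseline factor: alpha1 * (1 + 0.18*4) = 5.34 * 1.72,
  # minus the day-56 placebo effect, then cumulative DF offsets
  p <- po_params("RBSF", alpha1 = 5.34,
                 df = c(-2.34, -1.32, -1.37, -1.66, -2.27),
                 covariates = list(po_covariate("BASE_RBSF", "continuous",
                                                theta = 0.18),
                                   po_covariate("TNF", "categorical",
                                                theta = 0.14)),
                 slope_induction = 0.015, slope_maintenance = 0.001,
                 omega_sq = 3.47)
  ctx <- covariate_context(list(BASE_RBSF = 4, TNF = 0),
                           time_days = 56, induction_end_day = 56)
  lg <- cumulative_logits(p, ctx, eta = 0)
  expect_equal(lg, c(8.3448, 6.0048, 4.6848, 3.3148, 1.6548, -0.6152),
               tolerance = 1e-12)
  expect_true(all(diff(lg) < 0))
  # eta shifts all logits additively
  expect_equal(cumulative_logits(p, ctx, eta = 1.3), lg + 1.3)
  expect_equal(cumulative_logits(p, ctx, eta = -1.3), lg - 1.3)
  # null DF offsets collapse to a single shared logit
  p0 <- p; p0$df <- rep(-1e-12, 5)
  expect_equal(unname(cumulative_logits(p0, ctx, 0)),
               rep(lg[1], 6), tolerance = 1e-9)
})

test_that("category probabilities form a proper simplex", {
  lg <- c(8.3448, 6.0048, 4.6848, 3.3148, 1.6548, -0.6152)
  pr <- category_probabilities(lg)
  expect_length(pr, 7L)
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(pr[7], plogis(-0.6152), tolerance = 1e-12)
  expect_equal(pr[7], 0.3509, tolerance = 1e-4)
  # saturated two-cut-point case
  expect_equal(category_probabilities(c(20, -20)), c(0, 1, 0),
               tolerance = 1e-8)
  expect_error(category_probabilities(c(0, 0)), "decreasing")
  expect_error(category_probabilities(c(-1, 2)), "decreasing")
})

test_that("dropout probability follows the phase-specific logistic", {
  d <- dropout_params(-1.94, 0.68, -4.65, 0.84)
  expect_equal(dropout_probability(d, "induction", 0), plogis(-1.94))
  expect_equal(dropout_probability(d, "induction", 0), 0.1256,
               tolerance = 1e-3)
  expect_equal(dropout_probability(d, "induction", 4), plogis(0.78))
  expect_equal(dropout_probability(d, "induction", 4), 0.6857,
               tolerance = 1e-4)
  expect_equal(dropout_probability(d, "maintenance", 3), plogis(-4.65 + 2.52))
  # monotone nondecreasing in the score for positive slope
  expect_true(all(diff(dropout_probability(d, "maintenance", 0:6)) > 0))
  d0 <- dropout_params(-1, 0, -1, 0)
  expect_equal(dropout_probability(d0, "induction", 0:6),
               rep(plogis(-1), 7))
  expect_error(dropout_probability(d, "washout", 2), "unknown phase")
  expect_error(dropout_probability(d, "induction", 7), "out of range")
})

test_that("randomized parameters always give monotone logits and a simplex", {
  set.seed(301)
  for (i in 1:1000) {
    inst <- random_po_instance()
    lg <- cumulative_logits(inst$params, inst$ctx, inst$eta)
    expect_true(all(diff(lg) < 0))
    pr <- category_probabilities(lg)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # independent differencing oracle
    cum <- plogis(lg)
    oracle <- c(1 - cum[1], -diff(cum), cum[length(cum)])
    expect_equal(pr, oracle, tolerance = 1e-12)
  }
})
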