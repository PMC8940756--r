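designs <- build_designs()
model <- default_model()

test_that("conditional log-likelihood matches direct probability arithmetic", {
  p <- model$rbsf
  expect_equal(conditional_loglik(p, data.frame(DV = integer(),
                                                TIME_DAY = integer(),
                                                BASE_RBSF = integer(),
                                                TNF = integer()),
                                  eta = 0.5, induction_end_day = 56), 0)
  obs1 <- data.frame(DV = 6L, TIME_DAY = 56L, BASE_RBSF = 8, TNF = 0)
  # uncentered arithmetic shortcut: BASE_RBSF = 8 with center 4 gives the
  # 1.72 factor, so logit_6 = 5.34*1.72 - 0.84 - 8.96 = -0.6152
  expect_equal(conditional_loglik(p, obs1, 0, 56), log(plogis(-0.6152)),
               tolerance = 1e-12)
  obs0 <- obs1; obs0$DV <- 0L
  expect_equal(conditional_loglik(p, obs0, 0, 56),
               log(1 - plogis(8.3448)), tolerance = 1e-9)
  # saturation: a huge random effect drives the max-category probability to 1
  expect_gt(conditional_loglik(p, obs1, 30, 56), -1e-6)
  expect_lt(conditional_loglik(p, obs1, 30, 56), 0)
  expect_error(conditional_loglik(p, data.frame(DV = 7L, TIME_DAY = 14L,
                                                BASE_RBSF = 4, TNF = 0),
                                  0, 56), "outside")
})

test_that("adaptive Gauss-Hermite matches the brute-force grid oracle", {
  set.seed(77)
  for (i in 1:10) {
    inst <- random_po_instance()
    p <- inst$params
    p$omega_sq <- max(p$omega_sq, 0.05)
    nobs <- sample(1:6, 1)
    obs <- data.frame(DV = sample(0:p$max_score, nobs, replace = TRUE),
                      TIME_DAY = sort(sample(1:364, nobs)),
                      X1 = sample(0:6, 1), X2 = sample(0:1, 1))
    ll_gh <- marginal_loglik(p, obs, 56, method = "gh", nodes = 21)
    ll_tr <- trapz_marginal_ll(p, obs, 56)
    expect_equal(ll_gh, ll_tr, tolerance = 1e-6)
  }
})

test_that("degenerate and Laplace marginalizations behave as documented", {
  p <- model$rbsf
  obs <- data.frame(DV = c(3L, 5L), TIME_DAY = c(14L, 56L),
                    BASE_RBSF = 4, TNF = 1)
  p0 <- p; p0$omega_sq <- 0
  expect_equal(marginal_loglik(p0, obs, 56),
               conditional_loglik(p0, obs, 0, 56))
  # laplace is the one-node special case
  expect_equal(marginal_loglik(p, obs, 56, method = "laplace"),
               marginal_loglik(p, obs, 56, method = "gh", nodes = 1))
  # and close to, but distinct from, the full quadrature
  expect_equal(marginal_loglik(p, obs, 56, method = "laplace"),
               marginal_loglik(p, obs, 56), tolerance = 0.01)
  # node count converges monotonically on this instance
  lls <- sapply(c(3, 7, 11, 21), function(k)
    marginal_loglik(p, obs, 56, nodes = k))
  err <- abs(lls - trapz_marginal_ll(p, obs, 56))
  expect_true(all(diff(err) <= 1e-10))
})

test_that("with no random effect and single visits the fit reduces to ordinal regression", {
  skip_if_not_installed("MASS")
  set.seed(88)
  n <- 200
  B <- sample(0:6, n, replace = TRUE)
  truth <- po_params("RBSF", alpha1 = 2, df = c(-1, -0.8, -0.8, -1, -1.2),
                     covariates = list(po_covariate("BASE_RBSF",
                                                    "continuous",
                                                    theta = 0.15)),
                     omega_sq = 0)
  lg_mat <- sapply(1:6, function(m)
    2 * (1 + 0.15 * B) + c(0, cumsum(truth$df))[m])
  u <- runif(n)
  y <- rowSums(plogis(lg_mat) > u)
  dat <- data.frame(ID = sprintf("S%03d", 1:n), STUDY = "T",
                    TIME_DAY = 14L, ENDPOINT = "RBSF", DV = y,
                    PHASE = "IND", BASE_RBSF = B, BASE_ENDO = 2L,
                    BASE_PGA = 2L, TNF = 0L)
  toy_design <- list(T = build_designs(mini_config())[[1]])
  names(toy_design) <- "T"
  f <- fit_po_submodel(dat, "RBSF", toy_design,
                       covariates = list(po_covariate("BASE_RBSF",
                                                      "continuous")),
                       include_placebo = FALSE, fix_omega_sq = 0,
                       control = list(rel.tol = 1e-12))
  pol <- MASS::polr(factor(y, levels = 0:6) ~ B, method = "logistic",
                    control = list(reltol = 1e-12))
  # deviances agree
  expect_equal(f$ofv, pol$deviance, tolerance = 1e-4)
  # mapping: logit P(Y >= m) = (alpha1 + off_m) + alpha1*theta*B
  # vs polr's  -zeta_{m-1} + beta*B
  alpha1 <- f$estimates["alpha1"]
  offs <- c(0, cumsum(f$estimates[paste0("DF", 2:6)]))
  expect_equal(unname(alpha1 * f$estimates["BASE_RBSF"]),
               unname(coef(pol)["B"]), tolerance = 1e-3)
  expect_equal(unname(alpha1 + offs), unname(-pol$zeta), tolerance = 1e-3)
})

test_that("dropout MLE equals the two-point logistic closed form", {
  mk <- function(n1, k1, x1, n0, k0, x0) {
    data.frame(ID = sprintf("D%04d", 1:(n1 + n0)), STUDY = "T",
               TIME_DAY = 56L, ENDPOINT = "DROP",
               DV = c(rep(1L, k1), rep(0L, n1 - k1),
                      rep(1L, k0), rep(0L, n0 - k0)),
               PHASE = "IND", BASE_RBSF = 4L, BASE_ENDO = 2L,
               BASE_PGA = 2L, TNF = 0L,
               RBSF_VAL = c(rep(x1, n1), rep(x0, n0)))
  }
  drp <- rbind(mk(100, 40, 4L, 100, 10, 0L))
  rbsf <- drp; rbsf$ENDPOINT <- "RBSF"; rbsf$DV <- drp$RBSF_VAL
  rbsf$TIME_DAY <- 42L
  maint <- drp; maint$PHASE <- "MAINT"; maint$TIME_DAY <- 84L
  maint$ID <- paste0(maint$ID, "m")
  rbsf2 <- rbsf; rbsf2$ID <- paste0(rbsf2$ID, "m")
  dat <- rbind(drp, maint, rbsf, rbsf2)[, c("ID", "STUDY", "TIME_DAY",
                                            "ENDPOINT", "DV", "PHASE",
                                            "BASE_RBSF", "BASE_ENDO",
                                            "BASE_PGA", "TNF")]
  f <- fit_dropout_model(dat, designs)
  slope <- (qlogis(0.4) - qlogis(0.1)) / 4
  expect_equal(unname(f$estimates["slope_induction"]), slope,
               tolerance = 1e-8)
  expect_equal(unname(f$estimates["intercept_induction"]), qlogis(0.1),
               tolerance = 1e-8)
  expect_equal(unname(f$estimates["slope_maintenance"]), slope,
               tolerance = 1e-8)
  # degenerate event sets are a separation error
  none <- dat; none$DV[none$ENDPOINT == "DROP"] <- 0L
  expect_error(fit_dropout_model(none, designs), "separation")
})

test_that("sequential fitting is order-invariant and degrades gracefully", {
  cfg <- mini_config(40, 40)
  toy_designs <- build_designs(cfg)
  ch <- assemble_cohort(toy_designs, seed = 60)
  sim <- simulate_trial(ch, toy_designs, model, seed = 61)
  args <- list(designs = toy_designs, method = "laplace",
               compute_se = FALSE, control = list(rel.tol = 1e-10))
  f1 <- do.call(sequential_fit, c(list(sim), args))
  perm <- sim[order(rev(seq_len(nrow(sim)))), ]
  f2 <- do.call(sequential_fit, c(list(perm), args))
  expect_equal(f1$rbsf$ofv, f2$rbsf$ofv, tolerance = 1e-6)
  expect_equal(f1$endo$ofv, f2$endo$ofv, tolerance = 1e-6)
  expect_equal(f1$dropout$ofv, f2$dropout$ofv, tolerance = 1e-8)
  expect_s3_class(f1$model, "mcs_model")
  # dropping ENDO records skips the dependent fits but not the others
  noendo <- sim[sim$ENDPOINT != "ENDO", ]
  expect_message(f3 <- do.call(sequential_fit, c(list(noendo), args)),
                 "skipping")
  expect_null(f3$endo)
  expect_null(f3$pga)
  expect_false(is.null(f3$rbsf))
  expect_false(is.null(f3$dropout))
})

test_that("simulated null placebo slopes are recovered as null", {
  m <- model
  m$rbsf$slope_induction <- 0
  m$rbsf$slope_maintenance <- 0
  cfg <- mini_config(120, 120)
  toy_designs <- build_designs(cfg)
  ch <- assemble_cohort(toy_designs, seed = 70)
  sim <- simulate_trial(ch, toy_designs, m, seed = 71, dropout = FALSE)
  f <- fit_po_submodel(sim, "RBSF", toy_designs, method = "laplace")
  expect_true(!is.null(f$se))
  expect_lt(abs(f$estimates["slope_induction"]),
            2 * f$se["slope_induction"] + 1e-4)
  expect_lt(abs(f$estimates["slope_maintenance"]),
            2 * f$se["slope_maintenance"] + 1e-4)
})

test_that("bootstrap resampling is reproducible and degenerate data give zero SE", {
  base <- data.frame(ID = sprintf("I%03d", 1:60), STUDY = "T",
                     TIME_DAY = 56L, ENDPOINT = "DROP",
                     DV = rep(c(0L, 1L), 30), PHASE = "IND",
                     BASE_RBSF = 4L, BASE_ENDO = 2L, BASE_PGA = 2L,
                     TNF = 0L)
  rbsf <- base; rbsf$ENDPOINT <- "RBSF"; rbsf$TIME_DAY <- 42L
  rbsf$DV <- rep(c(2L, 5L, 5L, 2L), 15)   # imperfectly aligned covariate
  maint <- base; maint$PHASE <- "MAINT"; maint$TIME_DAY <- 84L
  dat <- rbind(base, rbsf, maint)
  b1 <- bootstrap_se(dat, 4, seed = 5, endpoint = "DROP",
                     designs = designs)
  b2 <- bootstrap_se(dat, 4, seed = 5, endpoint = "DROP",
                     designs = designs)
  expect_identical(b1$estimates, b2$estimates)
  # identical subjects: every resample is the same dataset, so SE = 0
  one <- data.frame(ID = "C", STUDY = "T", TIME_DAY = c(14L, 28L),
                    ENDPOINT = "RBSF", DV = c(3L, 5L), PHASE = "IND",
                    BASE_RBSF = 4L, BASE_ENDO = 2L, BASE_PGA = 2L,
                    TNF = 0L)
  clones <- do.call(rbind, lapply(1:40, function(k) {
    o <- one; o$ID <- paste0(o$ID, k); o
  }))
  toy_design <- list(T = build_designs(mini_config())[[1]])
  names(toy_design) <- "T"
  b3 <- suppressWarnings(
    bootstrap_se(clones, 3, seed = 6, endpoint = "RBSF",
                 designs = toy_design, covariates = list(),
                 include_placebo = FALSE, fix_omega_sq = 0,
                 method = "laplace"))
  expect_true(all(b3$se < 1e-6))
})
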