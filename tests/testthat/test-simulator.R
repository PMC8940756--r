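designs <- build_designs()
model <- default_model()

test_that("random effect draws have the requested variance structure", {
  expect_equal(draw_random_effects(0, 10, seed = 1),
               matrix(0, 10, 1), ignore_attr = TRUE)
  e <- draw_random_effects(c(rbsf = 3.47, endo = 1.01), 1e5, seed = 2)
  expect_equal(var(e[, "rbsf"]), 3.47, tolerance = 0.03)
  expect_equal(var(e[, "endo"]), 1.01, tolerance = 0.03)
  expect_equal(cor(e[, 1], e[, 2]), 0, tolerance = 0.02)
  expect_identical(e, draw_random_effects(c(rbsf = 3.47, endo = 1.01),
                                          1e5, seed = 2))
})

test_that("carry-forward covariate uses the same or most recent visit", {
  expect_equal(carry_forward_covariate(c(0, 14), c(5, 4), 14), 4)
  expect_equal(carry_forward_covariate(c(0, 14), c(5, 4), 20), 4)
  # sentinel rows are skipped
  expect_equal(carry_forward_covariate(c(0, 14), c(5, -99), 20), 5)
  expect_error(carry_forward_covariate(c(14, 28), c(5, 4), 7),
               "no eligible")
})

test_that("a saturating intercept forces every sampled score to the maximum", {
  m <- model
  for (nm in c("rbsf", "endo", "pga")) {
    m[[nm]]$alpha1 <- 50
    m[[nm]]$covariates <- list()
    m[[nm]]$slope_induction <- 0
    m[[nm]]$slope_maintenance <- 0
    m[[nm]]$omega_sq <- 0
  }
  subj <- data.frame(ID = "X-1", BASE_RBSF = 4, BASE_ENDO = 2,
                     BASE_PGA = 2, TNF = 0)
  obs <- simulate_subject(subj, designs[[1]], m, seed = 3)
  post <- obs[obs$TIME_DAY > 0, ]
  mx <- c(RBSF = 6L, ENDO = 3L, PGA = 3L)
  expect_true(all(post$DV == mx[post$ENDPOINT]))
})

test_that("single-visit frequencies match eta-marginalized brute-force integration", {
  # one symptom visit at day 56 for a reference patient (BASE = 4, TNF = 0)
  cfg <- mini_config()
  cfg$designs[[1]]$induction_weeks <- 8
  d <- build_designs(cfg)[[1]]
  p <- model$rbsf
  n <- 1e4
  subjects <- data.frame(ID = sprintf("S%05d", 1:n), STUDY = "TOY-IND",
                         BASE_RBSF = 4, BASE_ENDO = 2, BASE_PGA = 2,
                         TNF = 0)
  sim <- simulate_trial(subjects, list(`TOY-IND` = d), model, seed = 8,
                        dropout = FALSE)
  draws <- sim$DV[sim$ENDPOINT == "RBSF" & sim$TIME_DAY == 56]
  # brute-force 1-D integration over the random-effect distribution
  sig <- sqrt(p$omega_sq)
  grid <- seq(-8 * sig, 8 * sig, length.out = 4001)
  ctx <- covariate_context(list(BASE_RBSF = 4, TNF = 0), 56, 56)
  probs <- sapply(grid, function(e)
    category_probabilities(cumulative_logits(p, ctx, e)))
  w <- dnorm(grid, 0, sig); w <- w / sum(w)
  marg <- as.vector(probs %*% w)
  emp <- tabulate(draws + 1L, nbins = 7L) / n
  mc_se <- sqrt(marg * (1 - marg) / n)
  expect_true(all(abs(emp - marg) <= 3 * mc_se + 1e-12))
})

test_that("dropout events follow the end-of-induction logistic and censor with sentinels", {
  cfg <- mini_config()
  d <- build_designs(cfg)$`TOY-MAINT`
  n <- 1e4
  subjects <- data.frame(ID = sprintf("S%05d", 1:n), STUDY = "TOY-MAINT",
                         BASE_RBSF = 4, BASE_ENDO = 2, BASE_PGA = 2,
                         TNF = 0)
  # freeze all scores at 4 so the end-of-induction covariate is known
  m <- model
  sim <- simulate_trial(subjects, list(`TOY-MAINT` = d), m, seed = 12,
                        dropout = FALSE)
  sim$DV[sim$ENDPOINT == "RBSF"] <- 4L
  res <- apply_dropout(sim, d, m$dropout, seed = 13)
  ind_events <- res$observations[res$observations$ENDPOINT == "DROP" &
                                   res$observations$PHASE == "IND", ]
  expect_equal(nrow(ind_events), n)
  expect_equal(mean(ind_events$DV == 0), 1 - 0.6857, tolerance = 0.03)
  # sentinels appear only at planned visits strictly after dropout
  dd <- res$dropout
  obs <- res$observations
  m2 <- match(obs$ID, dd$ID)
  sent <- obs$DV == -99
  expect_true(all(obs$TIME_DAY[sent] > dd$dropout_day[m2][sent]))
  expect_true(all(obs$TIME_DAY[sent] %in%
                    c(d$rbsf_visit_days, d$endo_visit_days)))
  # no dropout before the end of induction
  expect_true(all(dd$dropout_day >= d$induction_end_day, na.rm = TRUE))
  # impossible dropout leaves the data untouched
  none <- apply_dropout(sim, d, dropout_params(-50, 0, -50, 0), seed = 14)
  expect_true(all(is.na(none$dropout$dropout_day)))
  expect_true(all(none$observations$DV != -99))
})

test_that("every planned visit yields exactly one row per scheduled endpoint", {
  ch <- assemble_cohort(designs, seed = 20, n_per_study = 30)
  sim <- simulate_trial(ch, designs, model, seed = 21)
  for (sid in names(designs)) {
    d <- designs[[sid]]
    ids <- ch$ID[ch$STUDY == sid]
    s <- sim[sim$STUDY == sid, ]
    for (ep in c("RBSF", "ENDO", "PGA")) {
      days <- if (ep == "RBSF") d$rbsf_visit_days else d$endo_visit_days
      cnt <- table(s$ID[s$ENDPOINT == ep], s$TIME_DAY[s$ENDPOINT == ep])
      expect_equal(dim(cnt), c(length(ids), length(days)))
      expect_true(all(cnt == 1L))
    }
  }
  expect_identical(sim, simulate_trial(ch, designs, model, seed = 21))
  sim2 <- simulate_trial(ch, designs, model, seed = 22)
  expect_false(identical(sim$DV, sim2$DV))
  # identical schedule skeleton for the score endpoints (dropout
  # indicator rows depend on the realized dropout times)
  a <- sim[sim$ENDPOINT != "DROP", c("ID", "TIME_DAY", "ENDPOINT")]
  b <- sim2[sim2$ENDPOINT != "DROP", c("ID", "TIME_DAY", "ENDPOINT")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("zero slopes without dropout give stationary per-visit score distributions", {
  m <- model
  m$rbsf$slope_induction <- 0
  m$rbsf$slope_maintenance <- 0
  cfg <- mini_config()
  d <- build_designs(cfg)$`TOY-IND`
  n <- 1e4
  subjects <- sample_baseline(d, n, seed = 30)
  subjects$ID <- sprintf("S%05d", 1:n); subjects$STUDY <- "TOY-IND"
  sim <- simulate_trial(subjects, list(`TOY-IND` = d), m, seed = 31,
                        dropout = FALSE)
  rb <- sim[sim$ENDPOINT == "RBSF" & sim$TIME_DAY > 0, ]
  chi <- suppressWarnings(chisq.test(table(rb$TIME_DAY, rb$DV)))
  expect_gt(chi$p.value, 0.01)
})

test_that("raising the score trajectory cannot reduce dropout", {
  cfg <- mini_config()
  d <- build_designs(cfg)$`TOY-MAINT`
  subjects <- sample_baseline(d, 800, seed = 40)
  subjects$ID <- sprintf("S%04d", 1:800); subjects$STUDY <- "TOY-MAINT"
  sim <- simulate_trial(subjects, list(`TOY-MAINT` = d), model, seed = 41,
                        dropout = FALSE)
  up <- sim
  rbsf_rows <- up$ENDPOINT == "RBSF"
  up$DV[rbsf_rows] <- pmin(up$DV[rbsf_rows] + 1L, 6L)
  r0 <- apply_dropout(sim, d, model$dropout, seed = 42)
  r1 <- apply_dropout(up, d, model$dropout, seed = 42)
  expect_gte(sum(!is.na(r1$dropout$dropout_day)),
             sum(!is.na(r0$dropout$dropout_day)))
})

test_that("the RB+SF/ENDO association strengthens with the linking coefficient", {
  cfg <- mini_config()
  d <- build_designs(cfg)$`TOY-IND`
  subjects <- sample_baseline(d, 1500, seed = 50)
  subjects$ID <- sprintf("S%04d", seq_len(nrow(subjects)))
  subjects$STUDY <- "TOY-IND"
  rho_at <- function(theta_pdv) {
    m <- model
    m$endo$covariates$PDV_RBSF$theta <- theta_pdv
    sim <- simulate_trial(subjects, list(`TOY-IND` = d), m, seed = 51,
                          dropout = FALSE)
    en <- sim[sim$ENDPOINT == "ENDO" & sim$TIME_DAY == 56, ]
    rb <- sim[sim$ENDPOINT == "RBSF" & sim$TIME_DAY == 56, ]
    spearman_corr(rb$DV[match(en$ID, rb$ID)], en$DV)
  }
  r_weak <- rho_at(0.2)
  r_strong <- rho_at(1.63)
  expect_gt(r_strong, 0)
  expect_gt(r_strong, r_weak)
})
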