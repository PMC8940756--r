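# Independent oracles and small fixtures used across the suite.

# Brute-force trapezoid marginalization of the conditional likelihood
# over an 8-sigma eta grid: per-visit cumulative logits are shifted by
# every grid value and the interval probabilities differenced directly.
trapz_marginal_ll <- function(params, observations, induction_end_day,
                              n_grid = 20001L) {
  sig <- sqrt(params$omega_sq)
  grid <- seq(-8 * sig, 8 * sig, length.out = n_grid)
  K <- params$max_score
  covcols <- setdiff(names(observations), c("DV", "TIME_DAY"))
  ll <- numeric(n_grid)
  for (r in seq_len(nrow(observations))) {
    ctx <- covariate_context(as.list(observations[r, covcols]),
                             observations$TIME_DAY[r], induction_end_day)
    lg <- cumulative_logits(params, ctx, 0)
    y <- observations$DV[r]
    u <- if (y >= 1) stats::plogis(lg[y] + grid) else 1
    v <- if (y < K) stats::plogis(lg[y + 1] + grid) else 0
    ll <- ll + log(u - v)
  }
  f <- exp(ll) * stats::dnorm(grid, 0, sig)
  log(pracma::trapz(grid, f))
}

# Exhaustive enumeration of the truncated joint baseline distribution
# under independent marginals (inclusion: ENDO >= 2, 6 <= MCS <= 12).
enum_truncated_baseline <- function(p_rbsf, p_endo, p_pga) {
  cells <- expand.grid(r = 0:6, e = 0:3, g = 0:3)
  cells$prob <- p_rbsf[cells$r + 1] * p_endo[cells$e + 1] *
    p_pga[cells$g + 1]
  tot <- cells$r + cells$e + cells$g
  cells$prob[cells$e < 2 | tot < 6 | tot > 12] <- 0
  cells$prob <- cells$prob / sum(cells$prob)
  cells
}

# Spearman's rho from first principles: average ranks, Pearson on ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A small two-study configuration (one induction-only, one with
# maintenance) for fast end-to-end runs; parameters are the packaged
# defaults.
mini_config <- function(n1 = 60L, n2 = 60L, baseline_correlation = NULL) {
  cfg <- read_model_config()
  cfg$designs <- list(
    list(study_id = "TOY-IND", n_enrolled = n1, induction_weeks = 8,
         tnf_prior_fraction = 0.3, endo_visit_weeks = c(0, 8),
         baseline = cfg$pooled_baseline),
    list(study_id = "TOY-MAINT", n_enrolled = n2, induction_weeks = 8,
         maintenance_weeks = 44, tnf_prior_fraction = 0.3,
         endo_visit_weeks = c(0, 8, 32, 52),
         baseline = cfg$pooled_baseline))
  if (!is.null(baseline_correlation)) {
    cfg$baseline_correlation <- baseline_correlation
  }
  cfg
}

# RB+SF parameter set with the packaged default values (centered
# baseline covariate), handy for constructing variants.
default_rbsf_params <- function() default_model()$rbsf

# Random but valid PO parameter/covariate draw for property suites.
random_po_instance <- function() {
  K <- sample(3:6, 1)
  params <- po_params(
    endpoint = "PO", alpha1 = stats::runif(1, -2, 6),
    df = -stats::rexp(K - 1, rate = 1) - 0.05,
    covariates = list(
      po_covariate("X1", "continuous", theta = stats::runif(1, 0, 0.3)),
      po_covariate("X2", "categorical", theta = stats::runif(1, -0.5, 1))),
    slope_induction = stats::runif(1, 0, 0.02),
    slope_maintenance = stats::runif(1, 0, 0.005),
    omega_sq = stats::rexp(1))
  ctx <- covariate_context(
    values = list(X1 = sample(0:6, 1), X2 = sample(0:1, 1)),
    time_days = sample(0:364, 1), induction_end_day = 56)
  list(params = params, ctx = ctx, eta = stats::rnorm(1, 0, 2))
}
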