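# Marginal likelihood of a proportional-odds submodel with a subject-level
# random intercept.  The conditional log-likelihood and its first two
# derivatives in eta are computed in closed form and vectorized over all
# observations; the subject-level marginal integral over eta is evaluated
# by adaptive Gauss-Hermite quadrature centred and scaled at the
# conditional mode (Laplace approximation = the 1-node special case).

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Stable log of F(lo) - F(hi) for the logistic cdf F, lo > hi.
# y = 0 rows have lo = +Inf (p = 1 - F(hi)); y = max rows have hi = -Inf.
log_interval_prob <- function(lo, hi) {
  out <- numeric(length(lo))
  a <- is.infinite(lo) & lo > 0      # y = 0
  b <- is.infinite(hi) & hi < 0      # y = max
  m <- !a & !b
  out[a] <- -softplus(hi[a])
  out[b] <- -softplus(-lo[b])
  out[m] <- hi[m] + log(expm1(lo[m] - hi[m])) -
    softplus(lo[m]) - softplus(hi[m])
  out
}

# First/second derivatives of log p wrt eta, given lo/hi (finite parts)
# and log p.  Returns list(g1, g2).
dlog_interval_prob <- function(lo, hi, logp) {
  u <- stats::plogis(lo); u1 <- stats::plogis(-lo)   # u1 = 1 - u, stable
  v <- stats::plogis(hi); v1 <- stats::plogis(-hi)
  du <- ifelse(is.finite(lo), u * u1, 0)
  dv <- ifelse(is.finite(hi), v * v1, 0)
  ddu <- ifelse(is.finite(lo), du * (u1 - u), 0)
  ddv <- ifelse(is.finite(hi), dv * (v1 - v), 0)
  p <- exp(logp)
  g1 <- (du - dv) / p
  g2 <- (ddu - ddv) / p - g1 * g1
  list(g1 = g1, g2 = g2)
}

# Prepared likelihood data for one endpoint: observation vectors plus a
# subject index.  `base_lo`/`base_hi` (cut-point logits without eta) are
# recomputed per parameter value by po_cutpoint_bounds().
po_prep <- function(y, subj, covdata, time_days, induction_end_day,
                    max_score) {
  stopifnot(length(y) == nrow(covdata), all(y >= 0), all(y <= max_score))
  sf <- factor(subj)
  list(y = as.integer(y), subj = as.integer(sf),
       n_subj = nlevels(sf), subj_levels = levels(sf),
       covdata = covdata, time_days = time_days,
       induction_end_day = induction_end_day, max_score = max_score,
       n_obs = length(y))
}

# Per-row lower/upper cut-point logits (excluding eta) for observed y.
po_cutpoint_bounds <- function(params, prep) {
  K <- params$max_score
  f <- po_factor(params, prep$covdata)
  plb <- placebo_effect(prep$time_days, prep$induction_end_day,
                        params$slope_induction, params$slope_maintenance)
  offs <- c(0, cumsum(params$df))
  if (params$covariate_scope == "alpha1") {
    base <- params$alpha1 * f + plb
    lo <- ifelse(prep$y >= 1L, base + offs[pmax(prep$y, 1L)], Inf)
    hi <- ifelse(prep$y < K, base + offs[pmin(prep$y, K - 1L) + 1L], -Inf)
  } else {
    am <- params$alpha1 + offs
    lo <- ifelse(prep$y >= 1L, f * am[pmax(prep$y, 1L)] + plb, Inf)
    hi <- ifelse(prep$y < K, f * am[pmin(prep$y, K - 1L) + 1L] + plb, -Inf)
  }
  list(lo = lo, hi = hi)
}

# Per-subject conditional log-likelihood at subject etas (vector of
# length n_subj), given precomputed bounds.  deriv = TRUE also returns
# per-subject first/second derivatives.
cond_ll_by_subject <- function(bounds, prep, eta, deriv = FALSE) {
  e <- eta[prep$subj]
  lo <- bounds$lo + ifelse(is.finite(bounds$lo), e, 0)
  hi <- bounds$hi + ifelse(is.finite(bounds$hi), e, 0)
  logp <- log_interval_prob(lo, hi)
  ll <- rowsum_vec(logp, prep$subj, prep$n_subj)
  if (!deriv) return(list(ll = ll))
  d <- dlog_interval_prob(lo, hi, logp)
  list(ll = ll,
       g1 = rowsum_vec(d$g1, prep$subj, prep$n_subj),
       g2 = rowsum_vec(d$g2, prep$subj, prep$n_subj))
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  r <- rowsum(x, idx)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

# Newton search for the per-subject mode of
# h(eta) = cond_ll(eta) - eta^2 / (2 omega_sq); the conditional
# log-likelihood is concave in eta, so undamped Newton with step clipping
# converges.  Returns list(mode, h2) with h2 = h''(mode) < 0.
po_find_modes <- function(bounds, prep, omega_sq, start = NULL,
                          max_iter = 50L, tol = 1e-10) {
  eta <- if (is.null(start)) numeric(prep$n_subj) else start
  inv_w <- 1 / omega_sq
  h2 <- rep(-inv_w, prep$n_subj)
  for (it in seq_len(max_iter)) {
    d <- cond_ll_by_subject(bounds, prep, eta, deriv = TRUE)
    g <- d$g1 - eta * inv_w
    h2 <- d$g2 - inv_w
    step <- -g / h2
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -4), 4)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  list(mode = eta, h2 = h2)
}

# Total marginal log-likelihood over subjects (vector of per-subject
# contributions).  `gh` holds $x/$w Gauss-Hermite nodes for weight
# exp(-z^2); nodes = 1 reproduces the Laplace approximation.
po_marginal_ll <- function(bounds, prep, omega_sq, gh, mode_cache = NULL) {
  if (omega_sq == 0) {
    return(cond_ll_by_subject(bounds, prep, numeric(prep$n_subj))$ll)
  }
  start <- if (!is.null(mode_cache)) mode_cache$mode else NULL
  md <- po_find_modes(bounds, prep, omega_sq, start = start)
  if (!is.null(mode_cache)) mode_cache$mode <- md$mode
  sdv <- 1 / sqrt(pmax(-md$h2, 1e-12))
  nq <- length(gh$x)
  lw <- matrix(NA_real_, prep$n_subj, nq)
  log_prior_const <- -0.5 * log(2 * pi * omega_sq)
  for (k in seq_len(nq)) {
    etak <- md$mode + sqrt(2) * sdv * gh$x[k]
    hk <- cond_ll_by_subject(bounds, prep, etak)$ll -
      etak^2 / (2 * omega_sq) + log_prior_const
    lw[, k] <- hk + gh$x[k]^2 + log(gh$w[k])
  }
  mx <- apply(lw, 1, max)
  mx + log(rowSums(exp(lw - mx))) + 0.5 * log(2) + log(sdv)
}

gh_rule <- function(method = c("gh", "laplace"), nodes = 21L) {
  method <- match.arg(method)
  if (method == "laplace") nodes <- 1L
  if (nodes == 1L) return(list(x = 0, w = sqrt(pi)))
  pracma::gaussHermite(nodes)
}

# ---- exported single-subject interfaces ----------------------------------

#' Conditional log-likelihood of one subject's observations
#'
#' Sum over visits of the log category probability of the observed score
#' given the subject random effect and the visit-specific covariates and
#' placebo effect.  Baseline (day 0) and sentinel rows must already be
#' excluded.
#'
#' @param params A [po_params()] object.
#' @param observations Data frame with columns `DV`, `TIME_DAY` and every
#'   covariate column named by `params$covariates`.
#' @param eta Subject random effect (logit units).
#' @param induction_end_day Day the induction phase ends.
#' @return The log-likelihood contribution (0 for zero observations).
#' @export
conditional_loglik <- function(params, observations, eta,
                               induction_end_day) {
  if (nrow(observations) == 0L) return(0)
  if (any(observations$DV < 0 | observations$DV > params$max_score)) {
    stop("observed score outside the 0-", params$max_score, " scale")
  }
  prep <- po_prep(observations$DV, rep(1L, nrow(observations)),
                  observations, observations$TIME_DAY, induction_end_day,
                  params$max_score)
  bounds <- po_cutpoint_bounds(params, prep)
  cond_ll_by_subject(bounds, prep, eta)$ll[1]
}

#' Marginal log-likelihood of one subject's observations
#'
#' Integrates the conditional likelihood over the subject random effect,
#' `log int exp(cond_ll(eta)) phi(eta; 0, omega_sq) d eta`, by adaptive
#' Gauss-Hermite quadrature centred at the conditional mode; `"laplace"`
#' is the 1-node special case.  With `omega_sq = 0` this equals the
#' conditional log-likelihood at `eta = 0`.
#'
#' @inheritParams conditional_loglik
#' @param method `"gh"` (adaptive Gauss-Hermite) or `"laplace"`.
#' @param nodes Number of quadrature nodes (default 21).
#' @return The marginal log-likelihood.
#' @export
marginal_loglik <- function(params, observations, induction_end_day,
                            method = c("gh", "laplace"), nodes = 21L) {
  gh <- gh_rule(match.arg(method), nodes)
  prep <- po_prep(observations$DV, rep(1L, nrow(observations)),
                  observations, observations$TIME_DAY, induction_end_day,
                  params$max_score)
  bounds <- po_cutpoint_bounds(params, prep)
  po_marginal_ll(bounds, prep, params$omega_sq, gh)[1]
}
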