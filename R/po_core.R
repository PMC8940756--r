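# Core proportional-odds arithmetic: covariate factors, placebo effect,
# cumulative logits, category probabilities and the dropout logistic.
# All functions here are pure and vectorized where it matters.

#' Multiplicative covariate factors
#'
#' Covariates act on the cut-point intercept through multiplicative
#' factors: `1 + theta * value` for continuous covariates and `1 + theta`
#' (flag set) or `1` (flag unset) for categorical covariates.
#'
#' @param theta Coefficient.
#' @param value Covariate value (continuous) — vectorized.
#' @param flag 0/1 indicator (categorical) — vectorized.
#' @return Numeric multiplier(s).  A non-positive factor for a continuous
#'   covariate is an error: it would flip the sign of the cut-point scale.
#' @export
covariate_factor_continuous <- function(theta, value) {
  f <- 1 + theta * value
  if (any(f <= 0)) {
    bad <- which(f <= 0)[1]
    stop(sprintf(
      "non-positive covariate factor (theta = %g, value = %g gives %g)",
      theta, value[bad], f[bad]))
  }
  f
}

#' @rdname covariate_factor_continuous
#' @export
covariate_factor_categorical <- function(theta, flag) {
  if (!all(flag %in% c(0, 1))) stop("categorical covariate flag must be 0/1")
  f <- 1 + theta * flag
  if (any(f <= 0)) stop("non-positive categorical covariate factor")
  f
}

#' Piecewise linear placebo effect
#'
#' The placebo response enters the logit scale as
#' `-slope_ind * TIME_ind - slope_maint * TIME_maint`, where `TIME_ind`
#' saturates at the end of induction and `TIME_maint` is time spent in the
#' maintenance phase.  Continuous in time with a kink exactly at the
#' induction/maintenance boundary; negative (score-lowering) for positive
#' slopes.
#'
#' @param time_days Time since first dose (days), vectorized.
#' @param induction_end_day Day the induction phase ends.
#' @param slope_ind,slope_maint Placebo slopes (1/day).
#' @return Logit-scale offset(s).
#' @export
placebo_effect <- function(time_days, induction_end_day, slope_ind,
                           slope_maint = 0) {
  stopifnot(all(time_days >= 0), induction_end_day >= 0)
  t_ind <- pmin(time_days, induction_end_day)
  t_mnt <- pmax(0, time_days - induction_end_day)
  -slope_ind * t_ind - slope_maint * t_mnt
}

#' Covariate context for a single model evaluation
#'
#' Bundles the covariate values needed to evaluate one subscore model at
#' one visit.  `values` must supply every column named by the model's
#' covariate terms (e.g. `BASE_RBSF`, `TNF`, `BASE_ENDO3`, `PDV_RBSF`,
#' `PDV_MMCS`).
#'
#' @param values Named list/vector of covariate values.
#' @param time_days Days since first dose.
#' @param induction_end_day Day induction ends.
#' @return An object of class `covariate_context`.
#' @export
covariate_context <- function(values, time_days, induction_end_day) {
  stopifnot(time_days >= 0)
  structure(list(values = as.list(values), time_days = time_days,
                 induction_end_day = induction_end_day),
            class = "covariate_context")
}

# Product of covariate factors for a row-wise covariate data.frame.
# Returns a vector of multipliers, one per row.
po_factor <- function(params, covdata) {
  f <- rep(1, nrow(covdata))
  for (cv in params$covariates) {
    x <- covdata[[cv$column]]
    if (is.null(x)) stop("missing covariate column: ", cv$column)
    f <- f * if (cv$type == "continuous")
      covariate_factor_continuous(cv$theta, x - (cv$center %||% 0))
    else covariate_factor_categorical(cv$theta, x)
  }
  f
}

# Vectorized logit matrix: rows = observations (covdata rows), columns =
# cut-points m = 1..max_score.  `eta` is per-row (already expanded).
po_logit_matrix <- function(params, covdata, time_days, induction_end_day,
                            eta = 0) {
  f <- po_factor(params, covdata)
  plb <- placebo_effect(time_days, induction_end_day,
                        params$slope_induction, params$slope_maintenance)
  offs <- c(0, cumsum(params$df))
  if (params$covariate_scope == "alpha1") {
    base <- params$alpha1 * f + plb + eta
    outer(base, rep(1, params$max_score)) +
      matrix(offs, nrow(covdata), params$max_score, byrow = TRUE)
  } else {
    alpha_m <- params$alpha1 + offs
    outer(f, alpha_m) + plb + eta
  }
}

#' Cumulative logits of a proportional-odds submodel
#'
#' Evaluates `logit P(Y >= m)` for `m = 1..max_score` at one covariate
#' context: the first cut-point is `alpha1` times the product of the
#' applicable covariate factors, plus the placebo effect and the subject
#' random effect; higher cut-points add the cumulative (negative) `DF`
#' increments, so the sequence is strictly decreasing.
#'
#' @param params A [po_params()] object.
#' @param ctx A [covariate_context()].
#' @param eta Subject random effect (logit units).
#' @return Numeric vector of logits, length `max_score`.
#' @export
cumulative_logits <- function(params, ctx, eta = 0) {
  stopifnot(inherits(params, "po_params"), inherits(ctx, "covariate_context"))
  drop(po_logit_matrix(params, as.data.frame(ctx$values), ctx$time_days,
                       ctx$induction_end_day, eta))
}

#' Category probabilities from cumulative logits
#'
#' Differences the inverse-logit cumulative probabilities into per-category
#' masses: `p_0 = 1 - expit(logit_1)`, `p_m = expit(logit_m) -
#' expit(logit_{m+1})`, `p_max = expit(logit_max)`.  Requires strictly
#' decreasing logits (guaranteed by the `DF < 0` parameterization).
#'
#' @param logits Strictly decreasing numeric vector (cut-points 1..max).
#' @return Probability vector over categories `0..max`; nonnegative and
#'   summing to 1.
#' @export
category_probabilities <- function(logits) {
  if (length(logits) < 1L || is.unsorted(rev(logits), strictly = TRUE)) {
    stop("cumulative logits must be strictly decreasing")
  }
  cum <- c(1, stats::plogis(logits), 0)
  -diff(cum)
}

#' Visit-level dropout probability
#'
#' Dropout follows a logistic regression on the most recent RB+SF
#' subscore with phase-specific intercept and slope: a single
#' end-of-induction event and a per-scheduled-visit maintenance hazard.
#'
#' @param params A [dropout_params()] object.
#' @param phase `"induction"` or `"maintenance"`.
#' @param rbsf Most recent RB+SF subscore (0-6), vectorized.
#' @return Dropout probability/probabilities.
#' @export
dropout_probability <- function(params, phase, rbsf) {
  stopifnot(inherits(params, "dropout_params"))
  if (any(rbsf < 0 | rbsf > 6)) stop("RB+SF subscore out of range 0-6")
  lin <- switch(phase,
    induction   = params$intercept_induction + params$slope_induction * rbsf,
    maintenance = params$intercept_maintenance + params$slope_maintenance * rbsf,
    stop("unknown phase label: ", phase))
  stats::plogis(lin)
}
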