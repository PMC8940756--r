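#' Covariate term of a proportional-odds submodel
#'
#' A covariate enters a subscore model as a multiplicative factor on the
#' cut-point intercept: `1 + theta * value` for continuous covariates and
#' `1 + theta` (when the flag is set) for categorical covariates.
#'
#' @param column Name of the dataset column supplying the covariate value.
#'   Reserved names understood by the simulator are `BASE_RBSF`, `BASE_PGA`,
#'   `BASE_ENDO3` (indicator that baseline ENDO is 3), `TNF`, `PDV_RBSF`
#'   (carried-forward RB+SF) and `PDV_MMCS` (carried-forward modified MCS).
#' @param type `"continuous"` or `"categorical"`.
#' @param theta Coefficient (unitless multiplier per covariate unit).
#' @param center Reference value subtracted from a continuous covariate
#'   before the factor is formed (`1 + theta * (value - center)`), so
#'   that `alpha_1` is the intercept of a reference patient.  Baseline
#'   subscore covariates default to the pooled baseline median in the
#'   packaged configuration; time-varying covariates are uncentered.
#' @return An object of class `po_covariate`.
#' @export
po_covariate <- function(column, type = c("continuous", "categorical"),
                         theta = 0, center = 0) {
  type <- match.arg(type)
  stopifnot(is.character(column), length(column) == 1L,
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(center), length(center) == 1L, is.finite(center))
  structure(list(column = column, type = type, theta = theta,
                 center = center),
            class = "po_covariate")
}

#' Parameters of one proportional-odds subscore model
#'
#' Cut-points are parameterized as `alpha_1` plus strictly negative
#' increments `DF_m` (`alpha_m = alpha_{m-1} + DF_m`), which guarantees
#' that the cumulative probabilities `P(Y >= m)` decrease in `m`.
#' Covariates multiply the `alpha_1` intercept (or, optionally, every
#' cut-point; see `covariate_scope`), the placebo effect is a piecewise
#' linear function of time with separate induction and maintenance slopes,
#' and a subject-level normal random effect with variance `omega_sq` acts
#' on the logit scale.
#'
#' @param endpoint Endpoint label, e.g. `"RBSF"`, `"ENDO"`, `"PGA"`.
#' @param alpha1 Logit-scale intercept for `P(Y >= 1)`.
#' @param df Numeric vector of negative increments `DF_2 .. DF_max`.
#' @param covariates List of [po_covariate()] terms.
#' @param slope_induction,slope_maintenance Placebo slopes (1/day); the
#'   placebo effect is `-slope_induction * TIME_ind - slope_maintenance *
#'   TIME_maint`.
#' @param omega_sq Variance of the subject random effect (>= 0).
#' @param covariate_scope `"alpha1"` (default): covariate factors multiply
#'   the first cut-point only, with the `DF` offsets added unscaled;
#'   `"all"`: factors multiply every cut-point `alpha_m`.
#' @return An object of class `po_params`.
#' @export
po_params <- function(endpoint, alpha1, df, covariates = list(),
                      slope_induction = 0, slope_maintenance = 0,
                      omega_sq = 0, covariate_scope = c("alpha1", "all")) {
  covariate_scope <- match.arg(covariate_scope)
  stopifnot(is.numeric(alpha1), length(alpha1) == 1L, is.finite(alpha1),
            is.numeric(df), length(df) >= 1L, all(is.finite(df)),
            is.numeric(omega_sq), length(omega_sq) == 1L, omega_sq >= 0,
            is.finite(slope_induction), is.finite(slope_maintenance))
  if (any(df >= 0)) {
    stop("all DF increments must be strictly negative (ordered cut-points)")
  }
  if (!all(vapply(covariates, inherits, logical(1), "po_covariate"))) {
    stop("`covariates` must be a list of po_covariate() terms")
  }
  names(covariates) <- vapply(covariates, `[[`, character(1), "column")
  structure(list(endpoint = endpoint, alpha1 = alpha1, df = df,
                 max_score = length(df) + 1L, covariates = covariates,
                 slope_induction = slope_induction,
                 slope_maintenance = slope_maintenance,
                 omega_sq = omega_sq, covariate_scope = covariate_scope),
            class = "po_params")
}

#' Parameters of the score-driven dropout model
#'
#' Dropout is a visit-level logistic regression on the most recent RB+SF
#' subscore, `logit(P_drop) = intercept + slope * (RB+SF)`, with separate
#' intercept/slope pairs for the single end-of-induction event and the
#' per-visit maintenance hazard.
#'
#' @param intercept_induction,slope_induction End-of-induction parameters
#'   (logit scale; slope per RB+SF point).
#' @param intercept_maintenance,slope_maintenance Maintenance-phase
#'   parameters.
#' @return An object of class `dropout_params`.
#' @export
dropout_params <- function(intercept_induction, slope_induction,
                           intercept_maintenance, slope_maintenance) {
  x <- c(intercept_induction, slope_induction,
         intercept_maintenance, slope_maintenance)
  stopifnot(is.numeric(x), length(x) == 4L, all(is.finite(x)))
  structure(list(intercept_induction = intercept_induction,
                 slope_induction = slope_induction,
                 intercept_maintenance = intercept_maintenance,
                 slope_maintenance = slope_maintenance),
            class = "dropout_params")
}

#' Reference parameter set of the linked Mayo Clinical Score model
#'
#' Returns the full linked model at the parameter estimates reported for
#' the pooled five-trial placebo/standard-of-care analysis: RB+SF, ENDO
#' and PGA proportional-odds submodels plus the two-phase dropout model.
#' The RB+SF model carries baseline RB+SF (continuous) and prior anti-TNF
#' exposure (categorical) covariate factors and a piecewise linear placebo
#' effect; the ENDO model is driven by baseline ENDO (categorical, level 3
#' vs 2) and the carried-forward RB+SF subscore; the PGA model is driven
#' by baseline PGA and the carried-forward modified MCS with its own
#' placebo effect.
#'
#' @param config Optional configuration list (as returned by
#'   [read_model_config()]) overriding the packaged defaults.
#' @return A list of class `mcs_model` with elements `rbsf`, `endo`,
#'   `pga` (each a [po_params()]) and `dropout` (a [dropout_params()]).
#' @export
default_model <- function(config = NULL) {
  if (is.null(config)) {
    config <- read_model_config()
  }
  model_from_config(config)
}

#' @rdname default_model
#' @param rbsf,endo,pga [po_params()] objects for the three subscores.
#' @param dropout A [dropout_params()] object.
#' @export
mcs_model <- function(rbsf, endo, pga, dropout) {
  stopifnot(inherits(rbsf, "po_params"), inherits(endo, "po_params"),
            inherits(pga, "po_params"), inherits(dropout, "dropout_params"))
  structure(list(rbsf = rbsf, endo = endo, pga = pga, dropout = dropout),
            class = "mcs_model")
}

#' Read the packaged (or a user) model/design configuration
#'
#' The configuration is a YAML file carrying the default model parameter
#' values and the designs of the five emulated trials (enrollment, phase
#' durations, visit spacing, baseline subscore marginals, prior-anti-TNF
#' fractions).
#'
#' @param path Path to a YAML configuration; defaults to the packaged file.
#' @return A named list.
#' @export
read_model_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "ucmayo",
                        mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

# Build an mcs_model from the parameters section of a config list.
model_from_config <- function(config) {
  p <- config$parameters
  mk_cov <- function(lst) {
    lapply(lst, function(cv) po_covariate(cv$column, cv$type, cv$theta,
                                          cv$center %||% 0))
  }
  mk_po <- function(endpoint, q) {
    po_params(endpoint = endpoint, alpha1 = q$alpha1, df = unlist(q$df),
              covariates = mk_cov(q$covariates),
              slope_induction = q$slope_induction %||% 0,
              slope_maintenance = q$slope_maintenance %||% 0,
              omega_sq = q$omega_sq,
              covariate_scope = config$covariate_scope %||% "alpha1")
  }
  mcs_model(rbsf = mk_po("RBSF", p$rbsf),
            endo = mk_po("ENDO", p$endo),
            pga  = mk_po("PGA",  p$pga),
            dropout = dropout_params(p$dropout$intercept_induction,
                                     p$dropout$slope_induction,
                                     p$dropout$intercept_maintenance,
                                     p$dropout$slope_maintenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.po_params <- function(x, ...) {
  cat("Proportional-odds submodel:", x$endpoint, "\n")
  cat("  alpha1 =", format(x$alpha1), " DF =",
      paste(format(x$df), collapse = ", "), "\n")
  if (length(x$covariates)) {
    for (cv in x$covariates) {
      cat(sprintf("  covariate %s (%s): theta = %g\n",
                  cv$column, cv$type, cv$theta))
    }
  }
  cat(sprintf("  placebo slopes: induction %g/day, maintenance %g/day\n",
              x$slope_induction, x$slope_maintenance))
  cat(sprintf("  Var(eta) = %g  [scope: %s]\n", x$omega_sq,
              x$covariate_scope))
  invisible(x)
}

#' @export
print.mcs_model <- function(x, ...) {
  cat("Linked Mayo Clinical Score model\n")
  for (nm in c("rbsf", "endo", "pga")) print(x[[nm]])
  d <- x$dropout
  cat(sprintf(
    "Dropout: logit(P) = %g + %g*RBSF (induction); %g + %g*RBSF (maint.)\n",
    d$intercept_induction, d$slope_induction,
    d$intercept_maintenance, d$slope_maintenance))
  invisible(x)
}
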