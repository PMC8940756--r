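# Maximum-likelihood estimation of the subscore and dropout models.

# Canonical covariate structure per endpoint; covariate centers follow
# the packaged configuration so fitted intercepts refer to the same
# reference patient as the default parameter set.
canonical_po_structure <- function(endpoint) {
  cen <- canonical_centers()
  switch(endpoint,
    RBSF = list(max_score = 6L, placebo = TRUE,
                covariates = list(
                  po_covariate("BASE_RBSF", "continuous",
                               center = cen["BASE_RBSF"]),
                  po_covariate("TNF", "categorical"))),
    ENDO = list(max_score = 3L, placebo = FALSE,
                covariates = list(
                  po_covariate("BASE_ENDO3", "categorical"),
                  po_covariate("PDV_RBSF", "continuous"))),
    PGA  = list(max_score = 3L, placebo = TRUE,
                covariates = list(
                  po_covariate("BASE_PGA", "continuous",
                               center = cen["BASE_PGA"]),
                  po_covariate("PDV_MMCS", "continuous"))),
    stop("unknown endpoint: ", endpoint))
}

canonical_centers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- read_model_config()$parameters
      out <- c(BASE_RBSF = 0, BASE_PGA = 0)
      for (q in p) for (cv in q$covariates) {
        if (cv$column %in% names(out)) out[cv$column] <- cv$center %||% 0
      }
      cache <<- out
    }
    cache
  }
})

# Carried-forward lookup: latest non-sentinel series value at or before
# each query time, per subject.
cf_lookup <- function(series_id, series_time, series_value,
                      query_id, query_time) {
  o <- order(series_id, series_time)
  sid <- series_id[o]; st <- series_time[o]; sv <- series_value[o]
  idx <- split(seq_along(sid), sid)
  out <- rep(NA_real_, length(query_id))
  for (id in unique(query_id)) {
    ii <- idx[[id]]
    if (is.null(ii)) next
    q <- which(query_id == id)
    pos <- findInterval(query_time[q], st[ii])
    ok <- pos >= 1L
    out[q[ok]] <- sv[ii][pos[ok]]
  }
  out
}

# Filter a long dataset down to the likelihood rows of one endpoint and
# derive the carried-forward covariate columns.
prepare_endpoint_rows <- function(dataset, endpoint, designs) {
  rows <- dataset[dataset$ENDPOINT == endpoint & dataset$TIME_DAY > 0 &
                    dataset$DV != SENTINEL, , drop = FALSE]
  if (nrow(rows) == 0L) return(rows)
  rbsf <- dataset[dataset$ENDPOINT == "RBSF" & dataset$DV != SENTINEL, ]
  if (endpoint %in% c("ENDO", "PGA")) {
    rows$PDV_RBSF <- cf_lookup(rbsf$ID, rbsf$TIME_DAY, rbsf$DV,
                               rows$ID, rows$TIME_DAY)
    rows <- rows[!is.na(rows$PDV_RBSF), , drop = FALSE]
  }
  if (endpoint == "ENDO") {
    rows$BASE_ENDO3 <- as.integer(rows$BASE_ENDO == 3L)
  }
  if (endpoint == "PGA") {
    # PGA enters the likelihood only at endoscopy visits; the modified
    # MCS covariate needs the same-visit ENDO observation
    en <- dataset[dataset$ENDPOINT == "ENDO" & dataset$DV != SENTINEL, ]
    key <- paste(rows$ID, rows$TIME_DAY)
    m <- match(key, paste(en$ID, en$TIME_DAY))
    rows <- rows[!is.na(m), , drop = FALSE]
    rows$PDV_MMCS <- rows$PDV_RBSF + en$DV[m[!is.na(m)]]
  }
  rows$IND_END <- vapply(designs[rows$STUDY], `[[`, numeric(1),
                         "induction_end_day")
  rows
}

# pack/unpack between the transformed optimizer vector and natural
# parameters.  DF increments use a negative-exponential transform
# (DF = -exp(xi)) and the random-effect variance a log transform.
po_par_map <- function(structure, placebo, free_df, fix_omega = NULL) {
  K <- structure$max_score
  nms <- c("alpha1", paste0("DF", 1L + which(free_df)),
           vapply(structure$covariates, `[[`, character(1), "column"),
           if (placebo) c("slope_induction", "slope_maintenance"),
           if (is.null(fix_omega)) "omega_sq")
  list(names = nms, K = K, free_df = free_df,
       n_cov = length(structure$covariates), placebo = placebo,
       fix_omega = fix_omega)
}

po_unpack <- function(theta, map, structure, covariate_scope) {
  K <- map$K
  i <- 1L
  alpha1 <- theta[i]; i <- i + 1L
  df <- rep(-15, K - 1L)                      # fixed bound for empty top categories
  nf <- sum(map$free_df)
  df[map$free_df] <- -exp(theta[seq.int(i, length.out = nf)])
  i <- i + nf
  covs <- structure$covariates
  for (j in seq_along(covs)) {
    covs[[j]]$theta <- theta[i]; i <- i + 1L
  }
  if (map$placebo) {
    s_ind <- theta[i]; s_mnt <- theta[i + 1L]; i <- i + 2L
  } else {
    s_ind <- 0; s_mnt <- 0
  }
  omega_sq <- if (is.null(map$fix_omega)) exp(theta[i]) else map$fix_omega
  po_params(endpoint = structure$endpoint %||% "PO", alpha1 = alpha1,
            df = df, covariates = covs, slope_induction = s_ind,
            slope_maintenance = s_mnt, omega_sq = omega_sq,
            covariate_scope = covariate_scope)
}

# Data-driven starting values: empirical cumulative logits for the
# cut-points, null covariate effects, small positive slopes, unit
# random-effect variance.
po_default_init <- function(y, map) {
  K <- map$K
  phat <- vapply(1:K, function(m) mean(y >= m), numeric(1))
  phat <- pmin(pmax(phat, 0.02), 0.98)
  a <- stats::qlogis(phat)
  alpha1 <- max(a[1], 0.5)
  df <- pmin(diff(a), -0.2)
  c(alpha1, log(-df[map$free_df]),
    rep(0.05, map$n_cov),
    if (map$placebo) c(0.003, 0.0005),
    if (is.null(map$fix_omega)) 0)
}

#' Fit one proportional-odds subscore model by maximum likelihood
#'
#' Maximizes the marginal likelihood (subject random effect integrated
#' out by adaptive Gauss-Hermite quadrature, or Laplace) over the
#' transformed parameters: cut-point increments via `DF = -exp(xi)` to
#' keep them negative, the random-effect variance via a log transform,
#' covariate coefficients and placebo slopes unconstrained.  Only
#' post-baseline, non-sentinel observations enter the likelihood;
#' baseline scores act purely as covariates.  For the ENDO and PGA
#' endpoints the carried-forward RB+SF / modified MCS covariates are
#' derived from the dataset; PGA observations enter only at endoscopy
#' visit days.  Cut-points above the highest observed category are fixed
#' at a -15 increment with a warning.
#'
#' @param dataset Long-format observation table (see [read_mcs_dataset()]
#'   or [simulate_trial()]).
#' @param endpoint `"RBSF"`, `"ENDO"` or `"PGA"`.
#' @param designs Named list of `uc_design` objects for the studies
#'   present (supplies induction end days).
#' @param covariates Optional list of [po_covariate()] terms replacing
#'   the endpoint's canonical covariate structure (used by the stepwise
#'   covariate engine).
#' @param include_placebo Override the canonical choice of whether the
#'   endpoint carries a placebo time effect.
#' @param method,nodes Marginalization method and quadrature size (see
#'   [marginal_loglik()]).
#' @param init Optional numeric vector of starting values on the
#'   transformed scale.
#' @param covariate_scope See [po_params()].
#' @param fix_omega_sq Optionally fix the random-effect variance at a
#'   value (e.g. 0 for a plain proportional-odds regression) instead of
#'   estimating it.
#' @param compute_se Compute curvature-based standard errors from a
#'   central finite-difference Hessian (default `TRUE`).
#' @param control Passed to [stats::nlminb()] (defaults: `rel.tol 1e-8`,
#'   `x.tol 1e-6`, `iter.max 500`).
#' @return A `fit_result` list: `estimates` (natural scale), `ofv`
#'   (-2 log-likelihood), `se`, `converged`, `n_subjects`,
#'   `n_observations`, `params` (fitted [po_params()]), `settings`.
#' @export
fit_po_submodel <- function(dataset, endpoint = c("RBSF", "ENDO", "PGA"),
                            designs = build_designs(), covariates = NULL,
                            include_placebo = NULL,
                            method = c("gh", "laplace"), nodes = 21L,
                            init = NULL,
                            covariate_scope = c("alpha1", "all"),
                            fix_omega_sq = NULL,
                            compute_se = TRUE, control = list()) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  covariate_scope <- match.arg(covariate_scope)
  structure_ <- canonical_po_structure(endpoint)
  structure_$endpoint <- endpoint
  if (!is.null(covariates)) structure_$covariates <- covariates
  placebo <- if (is.null(include_placebo)) structure_$placebo
             else include_placebo
  rows <- prepare_endpoint_rows(dataset, endpoint, designs)
  if (nrow(rows) == 0L) stop("no usable ", endpoint, " observations")
  K <- structure_$max_score
  y <- rows$DV
  if (any(y < 0 | y > K)) stop(endpoint, " observations outside 0-", K)
  free_df <- vapply(2:K, function(m) any(y >= m) && any(y < m), logical(1))
  if (!all(free_df)) {
    warning(endpoint, ": cut-point(s) ",
            paste(1L + which(!free_df), collapse = ", "),
            " unidentified (empty top categories); DF fixed at -15")
  }
  map <- po_par_map(structure_, placebo, free_df, fix_omega_sq)
  prep <- po_prep(y, rows$ID, rows, rows$TIME_DAY, rows$IND_END, K)
  mk_negll <- function(gh) {
    mode_cache <- new.env(parent = emptyenv())
    function(theta) {
      p <- try(po_unpack(theta, map, structure_, covariate_scope),
               silent = TRUE)
      if (inherits(p, "try-error")) return(1e10)
      b <- try(po_cutpoint_bounds(p, prep), silent = TRUE)
      if (inherits(b, "try-error")) return(1e10)
      ll <- sum(po_marginal_ll(b, prep, p$omega_sq, gh, mode_cache))
      if (!is.finite(ll)) 1e10 else -ll
    }
  }
  gh <- gh_rule(method, nodes)
  negll <- mk_negll(gh)
  start <- if (is.null(init)) po_default_init(y, map) else init
  ctl <- utils::modifyList(list(rel.tol = 1e-8, x.tol = 1e-6,
                                iter.max = 500L, eval.max = 2000L),
                           control)
  # two-stage optimization: a cheap Laplace (1-node) pre-fit travels the
  # long, possibly ill-conditioned approach path, then the full
  # quadrature objective refines from there
  if (method == "gh" && nodes > 1L && is.null(init)) {
    pre <- stats::nlminb(start, mk_negll(gh_rule("laplace")),
                         control = utils::modifyList(ctl,
                                                     list(rel.tol = 1e-7)))
    start <- pre$par
  }
  opt <- stats::nlminb(start, negll, control = ctl)
  attempt <- 0L
  while (opt$convergence != 0 && attempt < 2L) {
    attempt <- attempt + 1L
    if (grepl("iteration limit|function evaluation limit",
              opt$message %||% "")) {
      # budget exhaustion: continue from the current point
      alt <- stats::nlminb(opt$par, negll, control = ctl)
    } else {
      # genuine failure: restart from a deterministic jittered init
      jit <- with_seed(90000L + attempt,
                       start + stats::rnorm(length(start), 0, 0.3))
      alt <- stats::nlminb(jit, negll, control = ctl)
    }
    if (alt$objective <= opt$objective) opt <- alt
    if (opt$convergence == 0) break
  }
  params_hat <- po_unpack(opt$par, map, structure_, covariate_scope)
  est <- c(params_hat$alpha1,
           params_hat$df[map$free_df],
           vapply(params_hat$covariates, `[[`, numeric(1), "theta"),
           if (placebo) c(params_hat$slope_induction,
                          params_hat$slope_maintenance),
           if (is.null(fix_omega_sq)) params_hat$omega_sq)
  names(est) <- map$names
  se <- NULL
  if (compute_se) {
    se <- po_curvature_se(opt$par, negll, map)
  }
  structure(list(endpoint = endpoint, estimates = est,
                 ofv = 2 * opt$objective, loglik = -opt$objective,
                 se = se, converged = opt$convergence == 0,
                 n_subjects = prep$n_subj, n_observations = prep$n_obs,
                 params = params_hat,
                 settings = list(method = method, nodes = length(gh$x),
                                 iterations = opt$iterations,
                                 message = opt$message,
                                 restarts = attempt,
                                 free_df = free_df),
                 transformed = opt$par, map = map),
            class = "fit_result")
}

# Curvature-based SEs: central finite-difference Hessian of the negative
# marginal log-likelihood on the transformed scale (step 1e-4), mapped to
# the natural scale by the delta method.  Returns NULL when the Hessian
# is not positive definite.
po_curvature_se <- function(theta, negll, map, step = 1e-4) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  f0 <- negll(theta)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- step; ej[j] <- step
    if (i == j) {
      H[i, i] <- (negll(theta + ei) - 2 * f0 + negll(theta - ei)) / step^2
    } else {
      H[i, j] <- H[j, i] <-
        (negll(theta + ei + ej) - negll(theta + ei - ej) -
           negll(theta - ei + ej) + negll(theta - ei - ej)) / (4 * step^2)
    }
  }
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(diag(V) <= 0)) return(NULL)
  se_t <- sqrt(diag(V))
  # jacobian of natural wrt transformed: identity except DF (-exp) and
  # omega_sq (exp) whose derivative magnitude equals the natural value
  i <- 1L
  jac <- rep(1, p)
  i <- i + 1L
  nf <- sum(map$free_df)
  if (nf > 0) {
    jac[seq.int(i, length.out = nf)] <-
      exp(theta[seq.int(i, length.out = nf)])
    i <- i + nf
  }
  if (is.null(map$fix_omega)) jac[p] <- exp(theta[p])
  se <- abs(jac) * se_t
  names(se) <- map$names
  se
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of %s model: OFV = %.3f (%d subjects, %d observations)%s\n",
              x$endpoint, x$ofv, x$n_subjects, x$n_observations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates)
  if (!is.null(x$se)) tab$se <- x$se[names(x$estimates)]
  print(tab, digits = 4)
  invisible(x)
}

#' Fit the two-phase dropout model
#'
#' Two independent binary logistic regressions on the carried-forward
#' RB+SF subscore: one on the end-of-induction event records of studies
#' with a maintenance phase, one on the per-visit maintenance records.
#'
#' @param dataset Long-format table containing `DROP` indicator rows and
#'   the RB+SF observations supplying the covariate.
#' @param designs Named list of `uc_design` objects (unused beyond
#'   validation; kept for interface symmetry).
#' @return A `fit_result` with estimates `intercept_induction`,
#'   `slope_induction`, `intercept_maintenance`, `slope_maintenance`,
#'   phase-wise standard errors and `ofv` (summed deviance).
#' @export
fit_dropout_model <- function(dataset, designs = build_designs()) {
  drp <- dataset[dataset$ENDPOINT == "DROP", , drop = FALSE]
  if (nrow(drp) == 0L) stop("dataset contains no dropout (DROP) records")
  rbsf <- dataset[dataset$ENDPOINT == "RBSF" & dataset$DV != SENTINEL, ]
  drp$RBSF_CF <- cf_lookup(rbsf$ID, rbsf$TIME_DAY, rbsf$DV,
                           drp$ID, drp$TIME_DAY)
  drp <- drp[!is.na(drp$RBSF_CF), , drop = FALSE]
  fit_phase <- function(d, label) {
    if (nrow(d) == 0L) stop("no ", label, " dropout records")
    if (length(unique(d$DV)) < 2L) {
      stop("complete separation in ", label,
           " dropout records (all events identical)")
    }
    g <- stats::glm(DV ~ RBSF_CF, family = stats::binomial(), data = d)
    if (any(abs(stats::coef(g)) > 15)) {
      warning("near-separation in ", label, " dropout fit")
    }
    g
  }
  gi <- fit_phase(drp[drp$PHASE == "IND", ], "end-of-induction")
  gm <- fit_phase(drp[drp$PHASE == "MAINT", ], "maintenance")
  est <- c(intercept_induction = unname(stats::coef(gi)[1]),
           slope_induction = unname(stats::coef(gi)[2]),
           intercept_maintenance = unname(stats::coef(gm)[1]),
           slope_maintenance = unname(stats::coef(gm)[2]))
  se <- c(sqrt(diag(stats::vcov(gi))), sqrt(diag(stats::vcov(gm))))
  names(se) <- names(est)
  structure(list(endpoint = "DROP", estimates = est, se = se,
                 ofv = gi$deviance + gm$deviance,
                 loglik = -(gi$deviance + gm$deviance) / 2,
                 converged = gi$converged && gm$converged,
                 n_subjects = length(unique(drp$ID)),
                 n_observations = nrow(drp),
                 params = dropout_params(est[1], est[2], est[3], est[4]),
                 settings = list(method = "glm-binomial")),
            class = "fit_result")
}

#' Sequential fit of the full linked model
#'
#' Fits the submodels in the order the linkage requires: RB+SF first,
#' then ENDO (driven by the carried-forward observed RB+SF), then PGA
#' (driven by the observed modified MCS), then the dropout model.  The
#' submodels share no parameters.  Endpoints without usable records are
#' skipped with a diagnostic message.
#'
#' @inheritParams fit_po_submodel
#' @param ... Passed on to [fit_po_submodel()].
#' @return A list of class `sequential_fit` with elements `rbsf`, `endo`,
#'   `pga`, `dropout` (each a `fit_result` or `NULL`) and, when all four
#'   fits succeeded, `model`: the fitted `mcs_model` ready for simulation
#'   or VPC.
#' @export
sequential_fit <- function(dataset, designs = build_designs(), ...) {
  fits <- list(rbsf = NULL, endo = NULL, pga = NULL, dropout = NULL)
  fit_try <- function(expr, label) {
    r <- try(expr, silent = TRUE)
    if (inherits(r, "try-error")) {
      message("skipping ", label, " fit: ",
              conditionMessage(attr(r, "condition")))
      return(NULL)
    }
    r
  }
  fits$rbsf <- fit_try(fit_po_submodel(dataset, "RBSF", designs, ...),
                       "RB+SF")
  fits$endo <- fit_try(fit_po_submodel(dataset, "ENDO", designs, ...),
                       "ENDO")
  if (is.null(fits$endo)) {
    message("skipping PGA fit: modified MCS covariate needs ENDO records")
  } else {
    fits$pga <- fit_try(fit_po_submodel(dataset, "PGA", designs, ...),
                        "PGA")
  }
  fits$dropout <- fit_try(fit_dropout_model(dataset, designs), "dropout")
  if (!any(vapply(fits, is.null, logical(1)))) {
    fits$model <- mcs_model(fits$rbsf$params, fits$endo$params,
                            fits$pga$params, fits$dropout$params)
  }
  structure(fits, class = "sequential_fit")
}

#' @export
print.sequential_fit <- function(x, ...) {
  for (nm in c("rbsf", "endo", "pga", "dropout")) {
    if (is.null(x[[nm]])) cat(nm, ": not fitted\n") else print(x[[nm]])
  }
  invisible(x)
}

#' Nonparametric bootstrap of fitted parameters
#'
#' Resamples subjects with replacement (stratified by study, preserving
#' each trial's design and enrollment), refits the requested model on
#' every replicate, and summarizes the replicate estimates: the bootstrap
#' SE is their standard deviation, with 2.5/97.5 percentile intervals.
#' Replicates that fail or do not converge are dropped and counted.
#'
#' @param dataset Long-format observation table.
#' @param n_replicates Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param endpoint Endpoint to refit (`"RBSF"`, `"ENDO"`, `"PGA"` or
#'   `"DROP"` for the dropout model).
#' @param designs Named list of `uc_design` objects.
#' @param ... Passed on to the fitting function.
#' @return A list with `se`, `ci` (2.5/97.5 percentiles), `estimates`
#'   (replicate matrix) and `n_failed`.
#' @export
bootstrap_se <- function(dataset, n_replicates, seed = NULL,
                         endpoint = "RBSF", designs = build_designs(),
                         ...) {
  stopifnot(n_replicates >= 2L)
  u <- unique(dataset[, c("ID", "STUDY")])
  ids_by_study <- split(u$ID, u$STUDY)
  rows_by_id <- split(seq_len(nrow(dataset)), dataset$ID)
  with_seed(seed, {
    reps <- vector("list", n_replicates)
    n_failed <- 0L
    for (r in seq_len(n_replicates)) {
      take <- unlist(lapply(ids_by_study, function(ids)
        sample(ids, length(ids), replace = TRUE)), use.names = FALSE)
      idx <- rows_by_id[take]
      boot <- dataset[unlist(idx, use.names = FALSE), , drop = FALSE]
      boot$ID <- rep(sprintf("B%05d", seq_along(take)),
                     lengths(idx))
      fit <- try(if (endpoint == "DROP")
        fit_dropout_model(boot, designs)
      else fit_po_submodel(boot, endpoint, designs, compute_se = FALSE,
                           ...), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) {
        n_failed <- n_failed + 1L
      } else {
        reps[[r]] <- fit$estimates
      }
    }
    reps <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
    if (is.null(reps) || nrow(reps) < 2L) {
      stop("fewer than 2 converged bootstrap replicates")
    }
    list(se = apply(reps, 2, stats::sd),
         ci = apply(reps, 2, stats::quantile, probs = c(0.025, 0.975)),
         estimates = reps, n_failed = n_failed)
  })
}
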