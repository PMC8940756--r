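# Study designs and synthetic baseline cohorts emulating the five pooled
# placebo/SoC trials.

#' Build study design objects from a configuration
#'
#' Converts the `designs` section of a configuration (see
#' [read_model_config()]) into fully resolved design objects: visit
#' calendars in days, phase boundaries, baseline subscore marginals and
#' the prior-anti-TNF fraction.  Symptom (RB+SF) and PGA assessment visits
#' are scheduled every `rbsf_induction_weeks` during induction and every
#' `rbsf_maintenance_weeks` during maintenance; endoscopy visits follow
#' the per-study `endo_visit_weeks` calendar.
#'
#' @param config Configuration list; defaults to the packaged five-trial
#'   configuration.
#' @param baseline `"per_study"` (default) draws baseline subscores from
#'   each trial's own category marginals; `"pooled"` uses the pooled
#'   marginals of the configuration for every study.
#' @return A named list of `uc_design` objects.
#' @export
build_designs <- function(config = read_model_config(),
                          baseline = c("per_study", "pooled")) {
  baseline <- match.arg(baseline)
  specs <- config$designs
  if (length(specs) < 1L) stop("configuration names no studies")
  ids <- vapply(specs, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop("overlapping study ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  ind_step <- 7L * (config$visit_spacing$rbsf_induction_weeks %||% 2)
  mnt_step <- 7L * (config$visit_spacing$rbsf_maintenance_weeks %||% 4)
  rho <- config$baseline_correlation %||% 0
  designs <- lapply(specs, function(s) {
    marg <- if (baseline == "pooled") config$pooled_baseline else s$baseline
    new_design(study_id = s$study_id, n_enrolled = s$n_enrolled,
               induction_weeks = s$induction_weeks,
               maintenance_weeks = s$maintenance_weeks %||% NA_real_,
               endo_visit_weeks = unlist(s$endo_visit_weeks),
               tnf_prior_fraction = s$tnf_prior_fraction %||% 0,
               baseline = lapply(marg, unlist),
               baseline_correlation = rho,
               induction_step_days = ind_step,
               maintenance_step_days = mnt_step)
  })
  names(designs) <- ids
  designs
}

# Construct and validate a single design.
new_design <- function(study_id, n_enrolled, induction_weeks,
                       maintenance_weeks, endo_visit_weeks,
                       tnf_prior_fraction, baseline,
                       baseline_correlation = 0,
                       induction_step_days = 14L,
                       maintenance_step_days = 28L) {
  stopifnot(n_enrolled >= 1L, induction_weeks > 0,
            tnf_prior_fraction >= 0, tnf_prior_fraction <= 1,
            baseline_correlation > -0.5, baseline_correlation < 1)
  ind_end <- 7L * induction_weeks
  total <- if (is.na(maintenance_weeks)) ind_end else
    ind_end + 7L * maintenance_weeks
  rbsf_days <- seq(0L, ind_end, by = induction_step_days)
  if (!is.na(maintenance_weeks)) {
    rbsf_days <- c(rbsf_days,
                   seq(ind_end + maintenance_step_days, total,
                       by = maintenance_step_days))
  }
  endo_days <- 7L * endo_visit_weeks
  if (is.unsorted(endo_days, strictly = TRUE) || endo_days[1] != 0L) {
    stop("endoscopy visit weeks must be strictly increasing from week 0")
  }
  if (is.na(maintenance_weeks) && any(endo_days > ind_end)) {
    stop(sprintf(
      "study %s has no maintenance phase but endoscopy visits after week %d",
      study_id, induction_weeks))
  }
  if (any(endo_days > total)) {
    stop(sprintf("study %s: visits scheduled beyond end of study", study_id))
  }
  for (nm in c("rbsf", "endo", "pga")) {
    p <- baseline[[nm]]
    if (is.null(p) || any(p < 0) || sum(p) <= 0) {
      stop(sprintf("study %s: invalid baseline %s marginals", study_id, nm))
    }
  }
  structure(list(study_id = study_id, n_enrolled = as.integer(n_enrolled),
                 induction_weeks = induction_weeks,
                 maintenance_weeks = maintenance_weeks,
                 induction_end_day = ind_end, total_days = total,
                 rbsf_visit_days = as.integer(rbsf_days),
                 endo_visit_days = as.integer(endo_days),
                 pga_visit_days = as.integer(rbsf_days),
                 tnf_prior_fraction = tnf_prior_fraction,
                 baseline = baseline,
                 baseline_correlation = baseline_correlation),
            class = "uc_design")
}

#' @export
print.uc_design <- function(x, ...) {
  cat(sprintf("Study %s: n = %d, induction %g wk%s, prior-TNF %.0f%%\n",
              x$study_id, x$n_enrolled, x$induction_weeks,
              if (is.na(x$maintenance_weeks)) " (induction only)"
              else sprintf(" + maintenance %g wk", x$maintenance_weeks),
              100 * x$tnf_prior_fraction))
  cat("  RB+SF/PGA visits (days):",
      paste(x$rbsf_visit_days, collapse = " "), "\n")
  cat("  ENDO visits (days):",
      paste(x$endo_visit_days, collapse = " "), "\n")
  invisible(x)
}

#' Sample baseline subscore profiles for one study
#'
#' Baseline RB+SF, ENDO and PGA subscores are drawn from the study's
#' configured category marginals coupled by a Gaussian copula with
#' exchangeable correlation `design$baseline_correlation` (0 gives
#' independent draws), prior-anti-TNF exposure from a Bernoulli with the
#' study's fraction, and profiles violating the trial inclusion criteria
#' (total Mayo Clinical Score between 6 and 12 and baseline endoscopy
#' subscore of 2 or 3) are rejected and resampled.  The packaged default
#' correlation is calibrated so that the pooled baseline MCS standard
#' deviation matches the reported 1.63; truncation alone would
#' underdisperse the total score.
#'
#' @param design A `uc_design` object.
#' @param n Number of profiles required.
#' @param seed Optional integer seed (local to this call).
#' @return A data frame with columns `BASE_RBSF`, `BASE_ENDO`, `BASE_PGA`,
#'   `TNF` and `MCS0` (the baseline Mayo Clinical Score).
#' @export
sample_baseline <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "uc_design"), n >= 1L)
  p_rbsf <- design$baseline$rbsf / sum(design$baseline$rbsf)
  p_endo <- design$baseline$endo / sum(design$baseline$endo)
  p_pga  <- design$baseline$pga  / sum(design$baseline$pga)
  rho <- design$baseline_correlation %||% 0
  # analytic acceptance probability of the truncation region
  acc <- 0
  for (r in 0:6) for (e in 2:3) for (g in 0:3) {
    m <- r + e + g
    if (m >= 6 && m <= 12) acc <- acc + p_rbsf[r + 1] * p_endo[e + 1] * p_pga[g + 1]
  }
  if (acc <= 0) {
    stop(sprintf(
      "study %s: configured baseline marginals are inconsistent with the inclusion criteria",
      design$study_id))
  }
  # exchangeable 3x3 correlation; Cholesky factor for the copula draws
  L <- chol(matrix(rho, 3, 3) + diag(1 - rho, 3))
  qcat <- function(z, p) findInterval(stats::pnorm(z),
                                      cumsum(p)[-length(p)]) # 0-based
  with_seed(seed, {
    out <- matrix(NA_integer_, 0L, 3L)
    while (nrow(out) < n) {
      m <- max(32L, ceiling((n - nrow(out)) / acc * 1.2))
      z <- matrix(stats::rnorm(3L * m), m, 3L) %*% L
      r <- qcat(z[, 1], p_rbsf)
      e <- qcat(z[, 2], p_endo)
      g <- qcat(z[, 3], p_pga)
      tot <- r + e + g
      keep <- e >= 2L & tot >= 6L & tot <= 12L
      out <- rbind(out, cbind(r, e, g)[keep, , drop = FALSE])
    }
    out <- out[seq_len(n), , drop = FALSE]
    data.frame(BASE_RBSF = out[, 1], BASE_ENDO = out[, 2],
               BASE_PGA = out[, 3],
               TNF = as.integer(stats::runif(n) < design$tnf_prior_fraction),
               MCS0 = rowSums(out))
  })
}

#' Assemble a multi-study baseline cohort
#'
#' Draws baseline profiles for every design and stacks them into a single
#' cohort table, one row per subject, with study assignment and subject
#' identifiers.  Deterministic under a fixed seed.
#'
#' @param designs List of `uc_design` objects (see [build_designs()]).
#' @param seed Optional integer seed.
#' @param n_per_study Optional single count or named vector overriding each
#'   design's enrollment (useful for scaled-down simulation studies).
#' @return A data frame with columns `ID`, `STUDY`, `BASE_RBSF`,
#'   `BASE_ENDO`, `BASE_PGA`, `TNF`, `MCS0`.
#' @export
assemble_cohort <- function(designs, seed = NULL, n_per_study = NULL) {
  stopifnot(length(designs) >= 1L)
  with_seed(seed, {
    pieces <- lapply(designs, function(d) {
      n <- if (is.null(n_per_study)) d$n_enrolled
           else if (length(n_per_study) == 1L && is.null(names(n_per_study)))
             as.integer(n_per_study)
           else as.integer(n_per_study[[d$study_id]])
      prof <- sample_baseline(d, n)
      cbind(data.frame(ID = sprintf("%s-%04d", d$study_id, seq_len(n)),
                       STUDY = d$study_id), prof)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (restores the caller's RNG stream afterwards); with seed = NULL the
# current stream is used and advanced.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
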