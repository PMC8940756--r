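# Trial simulation under the linked model: longitudinal subscore
# trajectories, score-driven dropout, censoring and planned-visit
# imputation.  The engine is vectorized across the subjects of a study
# and sequential across visits, mirroring the model linkage (RB+SF drives
# ENDO and dropout; modified MCS drives PGA).

SENTINEL <- -99L

#' Draw subject-level random effects
#'
#' Independent mean-zero normal draws, one per subject per submodel, on
#' the logit scale.
#'
#' @param omega_sq Variance(s); a scalar or named vector (one entry per
#'   submodel).
#' @param n Number of subjects.
#' @param seed Optional integer seed (local to this call).
#' @return A matrix with `n` rows and one column per entry of `omega_sq`.
#' @export
draw_random_effects <- function(omega_sq, n, seed = NULL) {
  stopifnot(all(omega_sq >= 0), n >= 1L)
  with_seed(seed, {
    m <- vapply(omega_sq, function(v) stats::rnorm(n, 0, sqrt(v)),
                numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, names(omega_sq)))
  })
}

#' Carry forward a time-varying covariate
#'
#' Returns the value of a driving endpoint at the same or most recent
#' visit at or before `query_day`.  Sentinel-coded (post-dropout imputed)
#' entries are skipped.
#'
#' @param time,value Paired vectors defining the series.
#' @param query_day Day at which the covariate is needed.
#' @param sentinel Sentinel code marking imputed rows (default -99).
#' @return The carried-forward value.
#' @export
carry_forward_covariate <- function(time, value, query_day,
                                    sentinel = SENTINEL) {
  keep <- time <= query_day & value != sentinel
  if (!any(keep)) stop("no eligible covariate value at or before day ",
                       query_day)
  value[keep][which.max(time[keep])]
}

# Sample ordinal scores from a matrix of cumulative logits (rows =
# subjects, cols = cut-points): Y = number of cut-points whose cumulative
# probability exceeds a single uniform draw.
sample_po <- function(logit_mat) {
  u <- stats::runif(nrow(logit_mat))
  rowSums(stats::plogis(logit_mat) > u)
}

# Simulate the three subscore series for all subjects of one study on the
# complete planned-visit grid (no dropout).  `etas` is an n x 3 matrix
# (columns rbsf, endo, pga).  Returns a long data frame.
sim_scores_study <- function(subjects, design, model, etas) {
  n <- nrow(subjects)
  ind_end <- design$induction_end_day
  rb_days <- design$rbsf_visit_days
  en_days <- design$endo_visit_days
  covbase <- data.frame(BASE_RBSF = subjects$BASE_RBSF, TNF = subjects$TNF)
  rbsf <- matrix(NA_integer_, n, length(rb_days))
  for (j in seq_along(rb_days)) {
    t <- rb_days[j]
    rbsf[, j] <- if (t == 0L) subjects$BASE_RBSF else
      sample_po(po_logit_matrix(model$rbsf, covbase, t, ind_end,
                                etas[, 1]))
  }
  endo <- pga <- matrix(NA_integer_, n, length(en_days))
  for (j in seq_along(en_days)) {
    t <- en_days[j]
    if (t == 0L) {
      endo[, j] <- subjects$BASE_ENDO
      pga[, j] <- subjects$BASE_PGA
      next
    }
    # carried-forward RB+SF: same or most recent planned symptom visit
    jj <- max(which(rb_days <= t))
    pdv <- rbsf[, jj]
    endo[, j] <- sample_po(po_logit_matrix(
      model$endo,
      data.frame(BASE_ENDO3 = as.integer(subjects$BASE_ENDO == 3L),
                 PDV_RBSF = pdv),
      t, ind_end, etas[, 2]))
    mmcs <- pdv + endo[, j]
    pga[, j] <- sample_po(po_logit_matrix(
      model$pga,
      data.frame(BASE_PGA = subjects$BASE_PGA, PDV_MMCS = mmcs),
      t, ind_end, etas[, 3]))
  }
  long <- function(mat, days, endpoint) {
    data.frame(ID = rep(subjects$ID, times = length(days)),
               STUDY = design$study_id,
               TIME_DAY = rep(as.integer(days), each = n),
               ENDPOINT = endpoint,
               DV = as.integer(mat),
               PHASE = rep(ifelse(days <= ind_end, "IND", "MAINT"),
                           each = n))
  }
  out <- rbind(long(rbsf, rb_days, "RBSF"),
               long(endo, en_days, "ENDO"),
               long(pga, en_days, "PGA"))
  out$BASE_RBSF <- subjects$BASE_RBSF[match(out$ID, subjects$ID)]
  out$BASE_ENDO <- subjects$BASE_ENDO[match(out$ID, subjects$ID)]
  out$BASE_PGA <- subjects$BASE_PGA[match(out$ID, subjects$ID)]
  out$TNF <- subjects$TNF[match(out$ID, subjects$ID)]
  out
}

#' Simulate all subscore trajectories for one subject
#'
#' Draws the RB+SF series at the study's symptom visits, then ENDO at
#' endoscopy visits given the carried-forward simulated RB+SF, then PGA
#' given the simulated modified MCS, without dropout (see
#' [apply_dropout()]).
#'
#' @param subject A one-row data frame (or list) with `ID`, `BASE_RBSF`,
#'   `BASE_ENDO`, `BASE_PGA`, `TNF` and optionally `eta_rbsf`, `eta_endo`,
#'   `eta_pga` (drawn from the model variances when absent).
#' @param design A `uc_design`.
#' @param model An `mcs_model`.
#' @param seed Optional integer seed.
#' @return Long observation data frame (one row per visit per endpoint).
#' @export
simulate_subject <- function(subject, design, model, seed = NULL) {
  subject <- as.data.frame(as.list(subject))
  with_seed(seed, {
    etas <- if (all(c("eta_rbsf", "eta_endo", "eta_pga") %in%
                    names(subject))) {
      cbind(subject$eta_rbsf, subject$eta_endo, subject$eta_pga)
    } else {
      draw_random_effects(c(model$rbsf$omega_sq, model$endo$omega_sq,
                            model$pga$omega_sq), 1L)
    }
    sim_scores_study(subject, design, model, etas)
  })
}

#' Apply score-driven dropout to simulated observations
#'
#' For a study with a maintenance phase: a single Bernoulli dropout event
#' at the end-of-induction visit (induction parameters, RB+SF at that
#' visit), then, for subjects retained, an independent Bernoulli at each
#' scheduled maintenance symptom visit (maintenance parameters,
#' carried-forward RB+SF).  Observations strictly after the dropout day
#' are replaced by sentinel-valued imputed rows at the planned visits, and
#' `DROP` indicator rows (0/1) are appended at every at-risk visit.
#' Induction-only studies are administratively censored at the end of
#' induction with no model-based event.
#'
#' @param observations Long observation table for subjects of one study
#'   (complete planned visits, no prior censoring).
#' @param design The study's `uc_design`.
#' @param params A [dropout_params()] object.
#' @param seed Optional integer seed.
#' @return A list with `observations` (censored, with `DROP` rows) and
#'   `dropout` (data frame `ID`, `dropout_day`; `NA` when the subject
#'   completed the study).
#' @export
apply_dropout <- function(observations, design, params, seed = NULL) {
  ids <- unique(observations$ID)
  n <- length(ids)
  if (is.na(design$maintenance_weeks)) {
    return(list(observations = observations,
                dropout = data.frame(ID = ids, dropout_day = NA_integer_)))
  }
  rb_days <- design$rbsf_visit_days
  ind_end <- design$induction_end_day
  rb <- observations[observations$ENDPOINT == "RBSF", ]
  rbsf <- matrix(NA_integer_, n, length(rb_days))
  rbsf[cbind(match(rb$ID, ids), match(rb$TIME_DAY, rb_days))] <- rb$DV
  if (anyNA(rbsf)) stop("incomplete RB+SF grid: dropout needs all planned visits")

  with_seed(seed, {
    dropout_day <- rep(NA_integer_, n)
    drop_rows <- list()
    j_ind <- match(ind_end, rb_days)
    p <- dropout_probability(params, "induction", rbsf[, j_ind])
    ev <- stats::runif(n) < p
    dropout_day[ev] <- ind_end
    drop_rows[[1]] <- data.frame(ID = ids, TIME_DAY = ind_end,
                                 DV = as.integer(ev), PHASE = "IND")
    maint_j <- which(rb_days > ind_end)
    for (j in maint_j) {
      at_risk <- is.na(dropout_day)
      if (!any(at_risk)) break
      cf <- rbsf[at_risk, j]
      p <- dropout_probability(params, "maintenance", cf)
      ev <- stats::runif(sum(at_risk)) < p
      dropout_day[at_risk][ev] <- rb_days[j]
      drop_rows[[length(drop_rows) + 1L]] <-
        data.frame(ID = ids[at_risk], TIME_DAY = rb_days[j],
                   DV = as.integer(ev), PHASE = "MAINT")
    }
    dd <- dropout_day[match(observations$ID, ids)]
    censor <- !is.na(dd) & observations$TIME_DAY > dd
    observations$DV[censor] <- SENTINEL

    drp <- do.call(rbind, drop_rows)
    drp$STUDY <- design$study_id
    drp$ENDPOINT <- "DROP"
    base_cols <- c("BASE_RBSF", "BASE_ENDO", "BASE_PGA", "TNF")
    for (cc in base_cols) {
      drp[[cc]] <- observations[[cc]][match(drp$ID, observations$ID)]
    }
    drp <- drp[names(observations)]
    out <- rbind(observations, drp)
    out <- out[order(out$ID, out$TIME_DAY, out$ENDPOINT), ]
    rownames(out) <- NULL
    list(observations = out,
         dropout = data.frame(ID = ids, dropout_day = dropout_day))
  })
}

#' Simulate a full multi-study trial dataset
#'
#' Simulates every subject of the cohort at the complete planned visits of
#' its study, then applies the dropout model (unless disabled).  Output is
#' a long-format table with one row per subject-visit-endpoint, including
#' day-0 rows carrying the baseline subscores and 0/1 `DROP` indicator
#' rows at at-risk visits; deterministic under a fixed seed.
#'
#' @param cohort Cohort table from [assemble_cohort()].
#' @param designs Named list of `uc_design` objects covering every study
#'   in the cohort.
#' @param model An `mcs_model`.
#' @param seed Optional integer seed.
#' @param dropout Simulate score-driven dropout (default `TRUE`).
#' @return Long observation data frame; the per-subject random effects and
#'   dropout days are attached as the `"subjects"` attribute.
#' @export
simulate_trial <- function(cohort, designs, model, seed = NULL,
                           dropout = TRUE) {
  stopifnot(all(cohort$STUDY %in% names(designs)))
  with_seed(seed, {
    pieces <- list()
    subj_meta <- list()
    for (sid in unique(cohort$STUDY)) {
      d <- designs[[sid]]
      subjects <- cohort[cohort$STUDY == sid, , drop = FALSE]
      etas <- draw_random_effects(
        c(model$rbsf$omega_sq, model$endo$omega_sq, model$pga$omega_sq),
        nrow(subjects))
      obs <- sim_scores_study(subjects, d, model, etas)
      if (dropout) {
        res <- apply_dropout(obs, d, model$dropout)
        obs <- res$observations
        dday <- res$dropout$dropout_day[match(subjects$ID, res$dropout$ID)]
      } else {
        dday <- rep(NA_integer_, nrow(subjects))
      }
      pieces[[sid]] <- obs
      subj_meta[[sid]] <- data.frame(ID = subjects$ID, STUDY = sid,
                                     eta_rbsf = etas[, 1],
                                     eta_endo = etas[, 2],
                                     eta_pga = etas[, 3],
                                     dropout_day = dday)
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "subjects") <- do.call(rbind, c(subj_meta,
                                              make.row.names = FALSE))
    out
  })
}
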