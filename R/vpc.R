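# Simulation-based model evaluation: categorical and continuous visual
# predictive checks and rank-correlation diagnostics.

#' Spearman rank correlation of two ordinal series
#'
#' Spearman's rho with average ranks for ties, computed on paired values
#' after excluding sentinel-coded entries.
#'
#' @param x,y Paired numeric vectors (equal length >= 3 after sentinel
#'   removal).
#' @param sentinel Sentinel code to exclude (default -99).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y, sentinel = SENTINEL) {
  stopifnot(length(x) == length(y))
  keep <- x != sentinel & y != sentinel & !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 usable pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the series")
  }
  stats::cor(x, y, method = "spearman")
}

#' Rank correlations between linked endpoints at shared visits
#'
#' Pools baseline and post-baseline visits at which both members of a
#' pair were assessed (sentinel rows excluded) and computes Spearman's
#' rho between the RB+SF and ENDO subscores and between the modified MCS
#' (RB+SF + ENDO) and the PGA subscore.
#'
#' @param dataset Long-format observation table.
#' @return Named vector `c(rbsf_endo = ..., mmcs_pga = ...)`.
#' @export
shared_visit_correlations <- function(dataset) {
  ok <- dataset$DV != SENTINEL
  key <- function(d) paste(d$ID, d$TIME_DAY)
  en <- dataset[dataset$ENDPOINT == "ENDO" & ok, ]
  rb <- dataset[dataset$ENDPOINT == "RBSF" & ok, ]
  pg <- dataset[dataset$ENDPOINT == "PGA" & ok, ]
  m <- match(key(en), key(rb))
  en_rb <- rb$DV[m]
  rho1 <- spearman_corr(en$DV[!is.na(m)], en_rb[!is.na(m)])
  m2 <- match(key(pg), key(en))
  m3 <- match(key(pg), key(rb))
  use <- !is.na(m2) & !is.na(m3)
  mmcs <- rb$DV[m3[use]] + en$DV[m2[use]]
  rho2 <- spearman_corr(mmcs, pg$DV[use])
  c(rbsf_endo = unname(rho1), mmcs_pga = unname(rho2))
}

# Phase denominators for VPC proportions: everyone enrolled for the
# induction phase; for the maintenance phase, subjects of
# maintenance-capable studies that did not drop out at the end of
# induction (full enrollment of those studies when no dropout records
# are present).
vpc_denominators <- function(obs, designs) {
  u <- unique(obs[, c("ID", "STUDY")])
  has_maint <- !vapply(designs, function(d) is.na(d$maintenance_weeks),
                       logical(1))
  maint_ids <- u$ID[u$STUDY %in% names(designs)[has_maint]]
  ind_drop <- obs$ID[obs$ENDPOINT == "DROP" & obs$PHASE == "IND" &
                       obs$DV == 1L]
  c(IND = nrow(u), MAINT = length(setdiff(maint_ids, ind_drop)))
}

# Per-cell summary of one dataset: proportion of subjects in each
# category of each endpoint by (phase, week), plus dropout-event
# proportions; sentinel rows never contribute.
vpc_cat_summary <- function(obs, designs, max_scores) {
  den <- vpc_denominators(obs, designs)
  out <- list()
  for (ep in names(max_scores)) {
    d <- obs[obs$ENDPOINT == ep & obs$TIME_DAY > 0 & obs$DV != SENTINEL, ]
    if (nrow(d) == 0L) next
    wk <- d$TIME_DAY %/% 7L
    cats <- 0:max_scores[[ep]]
    tab <- table(factor(paste(d$PHASE, wk)),
                 factor(d$DV, levels = cats))
    cell <- strsplit(rownames(tab), " ")
    ph <- vapply(cell, `[`, character(1), 1L)
    week <- as.integer(vapply(cell, `[`, character(1), 2L))
    out[[ep]] <- data.frame(
      endpoint = ep,
      phase = rep(ph, times = length(cats)),
      week = rep(week, times = length(cats)),
      category = rep(cats, each = nrow(tab)),
      proportion = as.vector(tab) / den[ph])
  }
  dr <- obs[obs$ENDPOINT == "DROP", ]
  if (nrow(dr) > 0L) {
    wk <- dr$TIME_DAY %/% 7L
    agg <- stats::aggregate(dr$DV, by = list(phase = dr$PHASE, week = wk),
                            FUN = sum)
    out$DROP <- data.frame(endpoint = "DROP", phase = agg$phase,
                           week = agg$week, category = 1L,
                           proportion = agg$x / den[agg$phase])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Re-simulate the subjects of a dataset under `model` (complete planned
# visits, dropout applied and censored) n_replicates times and apply a
# summarizer to each replicate and to the observed data.
vpc_engine <- function(dataset, model, designs, n_replicates, seed,
                       summarize, dropout = TRUE) {
  cohort <- unique(dataset[, c("ID", "STUDY", "BASE_RBSF", "BASE_ENDO",
                               "BASE_PGA", "TNF")])
  obs_sum <- summarize(dataset)
  key <- function(s) paste(s$endpoint, s$phase, s$week, s$category,
                           s$stat %||% "")
  obs_key <- key(obs_sum)
  sims <- matrix(NA_real_, length(obs_key), n_replicates)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      sim <- simulate_trial(cohort, designs, model, dropout = dropout)
      s <- summarize(sim)
      m <- match(obs_key, key(s))
      sims[, r] <- ifelse(is.na(m), 0, s$proportion[m])
    }
  })
  obs_sum$lower <- apply(sims, 1, stats::quantile, probs = 0.025,
                         na.rm = TRUE)
  obs_sum$upper <- apply(sims, 1, stats::quantile, probs = 0.975,
                         na.rm = TRUE)
  obs_sum$observed <- obs_sum$proportion
  obs_sum$proportion <- NULL
  attr(obs_sum, "n_replicates") <- n_replicates
  obs_sum
}

#' Categorical visual predictive check
#'
#' Simulates `n_replicates` full datasets for the subjects and designs of
#' the supplied dataset (complete planned visits; observations after the
#' simulated dropout day censored), summarizes each replicate into
#' per-category proportions by nominal visit week with the
#' enrolled-in-phase denominator, and overlays the observed proportions
#' on the 95% prediction interval across replicates.  Dropout events are
#' summarized alongside the three subscores.
#'
#' @param dataset Long-format observation table (the "observed" data).
#' @param model An `mcs_model` (typically a fitted one).
#' @param designs Named list of `uc_design` objects.
#' @param n_replicates Number of simulation replicates (default 500).
#' @param seed Integer seed.
#' @return A `vpc_summary` data frame: `endpoint`, `phase`, `week`,
#'   `category`, `observed`, `lower`, `upper`.
#' @export
categorical_vpc <- function(dataset, model, designs = build_designs(),
                            n_replicates = 500L, seed = NULL) {
  stopifnot(n_replicates >= 1L)
  max_scores <- c(RBSF = model$rbsf$max_score, ENDO = model$endo$max_score,
                  PGA = model$pga$max_score)
  out <- vpc_engine(dataset, model, designs, n_replicates, seed,
                    function(d) vpc_cat_summary(d, designs, max_scores))
  class(out) <- c("vpc_summary", class(out))
  out
}

# Median and outer percentiles of the modified MCS per week among
# subjects remaining in the trial.
vpc_mmcs_summary <- function(obs) {
  ok <- obs$DV != SENTINEL
  en <- obs[obs$ENDPOINT == "ENDO" & ok & obs$TIME_DAY > 0, ]
  rb <- obs[obs$ENDPOINT == "RBSF" & ok, ]
  m <- match(paste(en$ID, en$TIME_DAY), paste(rb$ID, rb$TIME_DAY))
  use <- !is.na(m)
  d <- data.frame(week = en$TIME_DAY[use] %/% 7L,
                  phase = en$PHASE[use],
                  mmcs = en$DV[use] + rb$DV[m[use]])
  if (nrow(d) == 0L) {
    return(data.frame(endpoint = character(), phase = character(),
                      week = integer(), category = integer(),
                      stat = character(), proportion = numeric()))
  }
  pieces <- lapply(split(d, paste(d$phase, d$week)), function(g) {
    q <- stats::quantile(g$mmcs, probs = c(0.025, 0.5, 0.975))
    data.frame(endpoint = "MMCS", phase = g$phase[1], week = g$week[1],
               category = NA_integer_,
               stat = c("p2.5", "median", "p97.5"),
               proportion = unname(q))
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Continuous visual predictive check of the modified MCS
#'
#' The modified MCS (RB+SF + ENDO) is computed per subject-visit at
#' endoscopy weeks among subjects remaining in the trial; the observed
#' median and 2.5th/97.5th percentiles per week are overlaid on 95%
#' prediction bands from `n_replicates` re-simulations of the design.
#'
#' @inheritParams categorical_vpc
#' @return A `vpc_summary` data frame with a `stat` column
#'   (`median`, `p2.5`, `p97.5`) and columns `observed`, `lower`,
#'   `upper` (score units).
#' @export
continuous_vpc_modified_mcs <- function(dataset, model,
                                        designs = build_designs(),
                                        n_replicates = 500L,
                                        seed = NULL) {
  out <- vpc_engine(dataset, model, designs, n_replicates, seed,
                    vpc_mmcs_summary)
  class(out) <- c("vpc_summary", class(out))
  out
}

#' Plot a VPC summary
#'
#' Renders observed values over the simulated 95% prediction bands,
#' faceted by endpoint/category (categorical) or statistic (continuous).
#' Requires ggplot2.
#'
#' @param x A `vpc_summary` from [categorical_vpc()] or
#'   [continuous_vpc_modified_mcs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  facet <- if ("stat" %in% names(x) && !all(is.na(x$stat)))
    ggplot2::facet_wrap(~stat) else
    ggplot2::facet_grid(category ~ endpoint)
  ggplot2::ggplot(x, ggplot2::aes(x = week)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = observed), colour = "red") +
    facet +
    ggplot2::labs(x = "week", y = "proportion / score") +
    ggplot2::theme_minimal()
}
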