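# Stepwise covariate modeling by objective-function-value change.

#' Stepwise covariate selection on a subscore model
#'
#' Greedy forward selection followed by backward elimination of candidate
#' covariate factors on the cut-point intercept.  At each forward step
#' the candidate giving the largest drop in OFV is added if the drop
#' exceeds `forward_threshold` (default 3.84, chi-square p < 0.05 for one
#' degree of freedom); in the backward pass a selected covariate is
#' removed unless dropping it raises the OFV by more than
#' `backward_threshold` (default 10.8, p < 0.001).
#'
#' @inheritParams fit_po_submodel
#' @param candidates List of [po_covariate()] terms to screen.
#' @param base_covariates Covariates always kept in the model; defaults
#'   to the endpoint's canonical baseline covariate(s) minus the
#'   candidates under test.
#' @param forward_threshold,backward_threshold OFV-change thresholds; the
#'   packaged configuration carries the defaults.
#' @param ... Passed on to [fit_po_submodel()].
#' @return An `scm_report`: data frames `forward_steps` and
#'   `backward_steps` (candidate, delta_ofv, kept/removed flag),
#'   `final_covariates` (column names), and the final `fit`.
#' @export
scm_select <- function(dataset, endpoint = "RBSF", candidates,
                       base_covariates = NULL,
                       designs = build_designs(),
                       forward_threshold = NULL, backward_threshold = NULL,
                       ...) {
  thr <- read_model_config()$scm_thresholds
  forward_threshold <- forward_threshold %||% thr$forward %||% 3.84
  backward_threshold <- backward_threshold %||% thr$backward %||% 10.8
  if (is.null(base_covariates)) {
    base_covariates <- canonical_po_structure(endpoint)$covariates
    cand_cols <- vapply(candidates, `[[`, character(1), "column")
    base_covariates <- Filter(
      function(cv) !(cv$column %in% cand_cols), base_covariates)
  }
  col_of <- function(cvs) vapply(cvs, `[[`, character(1), "column")
  refit <- function(cvs) {
    fit_po_submodel(dataset, endpoint, designs, covariates = cvs,
                    compute_se = FALSE, ...)
  }
  base_fit <- refit(base_covariates)
  selected <- list()
  remaining <- candidates
  fwd <- list()
  current <- base_fit
  while (length(remaining) > 0L) {
    ofvs <- vapply(remaining, function(cv) {
      refit(c(base_covariates, selected, list(cv)))$ofv
    }, numeric(1))
    delta <- current$ofv - ofvs
    best <- which.max(delta)
    keep <- delta[best] > forward_threshold
    fwd[[length(fwd) + 1L]] <- data.frame(
      candidate = col_of(remaining)[best], delta_ofv = delta[best],
      kept = keep)
    if (!keep) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    current <- refit(c(base_covariates, selected))
  }
  bwd <- list()
  repeat {
    if (length(selected) == 0L) break
    deltas <- vapply(seq_along(selected), function(i) {
      refit(c(base_covariates, selected[-i]))$ofv - current$ofv
    }, numeric(1))
    worst <- which.min(deltas)
    if (deltas[worst] > backward_threshold) {
      bwd[[length(bwd) + 1L]] <- data.frame(
        candidate = col_of(selected)[worst], delta_ofv = deltas[worst],
        removed = FALSE)
      break
    }
    bwd[[length(bwd) + 1L]] <- data.frame(
      candidate = col_of(selected)[worst], delta_ofv = deltas[worst],
      removed = TRUE)
    selected <- selected[-worst]
    current <- refit(c(base_covariates, selected))
  }
  structure(list(
    forward_steps = if (length(fwd)) do.call(rbind, fwd) else
      data.frame(candidate = character(), delta_ofv = numeric(),
                 kept = logical()),
    backward_steps = if (length(bwd)) do.call(rbind, bwd) else
      data.frame(candidate = character(), delta_ofv = numeric(),
                 removed = logical()),
    final_covariates = col_of(selected),
    base_covariates = col_of(base_covariates),
    thresholds = c(forward = forward_threshold,
                   backward = backward_threshold),
    fit = current), class = "scm_report")
}

#' @export
print.scm_report <- function(x, ...) {
  cat("Stepwise covariate modeling (forward >",
      x$thresholds["forward"], "/ backward >",
      x$thresholds["backward"], "OFV units)\n")
  cat("Forward steps:\n"); print(x$forward_steps)
  cat("Backward steps:\n"); print(x$backward_steps)
  cat("Final covariates:",
      paste(c(x$base_covariates, x$final_covariates), collapse = ", "),
      "\n")
  invisible(x)
}
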