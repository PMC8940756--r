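# Long-format dataset reader/writer and the command pipeline tying the
# stages together.

DATASET_COLUMNS <- c("ID", "STUDY", "TIME_DAY", "ENDPOINT", "DV", "PHASE",
                     "BASE_RBSF", "BASE_ENDO", "BASE_PGA", "TNF")
ENDPOINT_LEVELS <- c("RBSF", "ENDO", "PGA", "DROP")
ENDPOINT_MAX <- c(RBSF = 6L, ENDO = 3L, PGA = 3L, DROP = 1L)

#' Validate a long-format observation table
#'
#' Checks the column set, endpoint labels, score ranges (sentinel -99
#' permitted for non-DROP rows), phase labels, key uniqueness of
#' `(ID, TIME_DAY, ENDPOINT)` and constancy of baseline covariates
#' within subject.  Violations are reported with row numbers.
#'
#' @param dataset Data frame to validate.
#' @return The dataset, invisibly, on success.
#' @export
validate_mcs_dataset <- function(dataset) {
  missing_cols <- setdiff(DATASET_COLUMNS, names(dataset))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!dataset$ENDPOINT %in% ENDPOINT_LEVELS)
  if (length(bad)) {
    stop("unknown endpoint label in rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  mx <- ENDPOINT_MAX[dataset$ENDPOINT]
  ok_range <- (dataset$DV >= 0 & dataset$DV <= mx) |
    (dataset$DV == SENTINEL & dataset$ENDPOINT != "DROP")
  if (any(!ok_range)) {
    stop("DV out of range in rows: ",
         paste(utils::head(which(!ok_range), 5), collapse = ", "))
  }
  if (any(!dataset$PHASE %in% c("IND", "MAINT"))) {
    stop("PHASE must be IND or MAINT")
  }
  key <- paste(dataset$ID, dataset$TIME_DAY, dataset$ENDPOINT)
  if (anyDuplicated(key)) {
    stop("duplicate (ID, TIME_DAY, ENDPOINT) keys in rows: ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  for (cc in c("BASE_RBSF", "BASE_ENDO", "BASE_PGA", "TNF")) {
    n_per_id <- tapply(dataset[[cc]], dataset$ID,
                       function(v) length(unique(v)))
    if (any(n_per_id > 1L)) {
      stop(cc, " varies within subject(s): ",
           paste(utils::head(names(n_per_id)[n_per_id > 1L], 5),
                 collapse = ", "))
    }
  }
  invisible(dataset)
}

#' Read / write the long-format observation table
#'
#' Comma-delimited UTF-8 with the fixed header `ID, STUDY, TIME_DAY,
#' ENDPOINT, DV, PHASE, BASE_RBSF, BASE_ENDO, BASE_PGA, TNF`; days (not
#' weeks) on disk; sentinel `-99` marks imputed post-dropout rows.  The
#' table is type- and invariant-checked on read.
#'
#' @param path File path.
#' @return `read_mcs_dataset`: the validated data frame.
#' @export
read_mcs_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("TIME_DAY", "DV", "BASE_RBSF", "BASE_ENDO", "BASE_PGA",
               "TNF")) {
    if (cc %in% names(d)) d[[cc]] <- as.integer(d[[cc]])
  }
  validate_mcs_dataset(d)
  message(sprintf("read %d rows, %d subjects from %s",
                  nrow(d), length(unique(d$ID)), path))
  d
}

#' @rdname read_mcs_dataset
#' @param dataset Validated observation table.
#' @export
write_mcs_dataset <- function(dataset, path) {
  validate_mcs_dataset(dataset)
  utils::write.csv(dataset[DATASET_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Provenance block written next to every artifact.
provenance <- function(config_path, seed) {
  list(seed = seed,
       config = config_path %||% "packaged default",
       config_md5 = if (!is.null(config_path))
         unname(tools::md5sum(config_path)) else NA_character_,
       package_version = as.character(utils::packageVersion("ucmayo")),
       created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
}

#' Run one pipeline command
#'
#' Programmatic entry point tying the stages into a reproducible
#' pipeline; each command reads its inputs from disk, runs the package
#' functions, and writes its artifacts (CSV/YAML) plus a provenance
#' sidecar carrying the seed, configuration hash and package version.
#'
#' Commands: `cohort` (baseline cohort CSV), `simulate` (long dataset
#' CSV; needs a cohort), `fit` (sequential fit parameter table; needs a
#' dataset), `vpc` (categorical VPC summary; needs a dataset and a
#' parameter file or the packaged defaults), `scm` (stepwise covariate
#' report), `bootstrap` (bootstrap SE table).
#'
#' @param name Command name.
#' @param config Optional path to a YAML configuration (packaged default
#'   otherwise).
#' @param seed Integer seed; recorded in the output metadata.
#' @param out Output file path (directory is created).
#' @param data,cohort,params Paths to upstream artifacts, where the
#'   command requires them.
#' @param nrep Replicates for `vpc` / `bootstrap`.
#' @param ... Further arguments passed to the underlying function.
#' @return The path of the main artifact, invisibly.
#' @export
run_command <- function(name = c("cohort", "simulate", "fit", "vpc",
                                 "scm", "bootstrap"),
                        config = NULL, seed = 1L, out,
                        data = NULL, cohort = NULL, params = NULL,
                        nrep = NULL, ...) {
  name <- match.arg(name)
  cfg <- read_model_config(config)
  designs <- build_designs(cfg)
  model <- model_from_config(cfg)
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path %||% "")) {
      stop("command '", name, "' needs an existing ", what, " file")
    }
    path
  }
  result_meta <- list()
  if (name == "cohort") {
    ch <- assemble_cohort(designs, seed = seed)
    utils::write.csv(ch, out, row.names = FALSE, quote = FALSE)
  } else if (name == "simulate") {
    ch <- utils::read.csv(need(cohort, "cohort"), stringsAsFactors = FALSE)
    sim <- simulate_trial(ch, designs, model, seed = seed, ...)
    write_mcs_dataset(sim, out)
  } else if (name == "fit") {
    ds <- read_mcs_dataset(need(data, "dataset"))
    fits <- sequential_fit(ds, designs, ...)
    tabs <- lapply(Filter(Negate(is.null),
                          fits[c("rbsf", "endo", "pga", "dropout")]),
                   function(f) {
      data.frame(endpoint = f$endpoint, parameter = names(f$estimates),
                 estimate = unname(f$estimates),
                 se = if (is.null(f$se)) NA_real_
                      else unname(f$se[names(f$estimates)]),
                 ofv = f$ofv, converged = f$converged)
    })
    utils::write.csv(do.call(rbind, c(tabs, make.row.names = FALSE)),
                     out, row.names = FALSE)
  } else if (name == "vpc") {
    ds <- read_mcs_dataset(need(data, "dataset"))
    if (!is.null(params)) {
      cfg2 <- read_model_config(need(params, "parameter"))
      model <- model_from_config(cfg2)
    } else if (is.null(config)) {
      stop("vpc needs a fitted/provided parameter file or configuration")
    }
    v <- categorical_vpc(ds, model, designs,
                         n_replicates = nrep %||% cfg$vpc$n_replicates
                           %||% 500L,
                         seed = seed)
    utils::write.csv(v, out, row.names = FALSE)
  } else if (name == "scm") {
    ds <- read_mcs_dataset(need(data, "dataset"))
    rep_ <- scm_select(ds, designs = designs, ...)
    utils::write.csv(rbind(
      cbind(pass = "forward", rep_$forward_steps,
            flag = rep_$forward_steps$kept)[, c("pass", "candidate",
                                                "delta_ofv", "flag")],
      cbind(pass = "backward", rep_$backward_steps,
            flag = !rep_$backward_steps$removed)[, c("pass", "candidate",
                                                     "delta_ofv", "flag")]),
      out, row.names = FALSE)
    result_meta$final_covariates <- rep_$final_covariates
  } else if (name == "bootstrap") {
    ds <- read_mcs_dataset(need(data, "dataset"))
    b <- bootstrap_se(ds, n_replicates = nrep %||% 100L, seed = seed,
                      designs = designs, ...)
    utils::write.csv(data.frame(parameter = names(b$se), se = b$se,
                                lower = b$ci[1, ], upper = b$ci[2, ],
                                n_failed = b$n_failed),
                     out, row.names = FALSE)
  }
  meta <- c(provenance(config, seed), list(command = name), result_meta)
  yaml::write_yaml(meta, paste0(out, ".meta.yaml"))
  invisible(out)
}
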