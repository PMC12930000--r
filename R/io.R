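#' Run configuration for a single model fit
#'
#' Collects everything needed to reproduce a fit from a CSV file: column
#' names, family, constraint, augmentation request, prior overrides, sampler
#' settings, seed and output directory.
#'
#' @param input path to a CSV file with a header row.
#' @param outcome,predictor column names for the outcome and predictor.
#' @param covariates optional character vector of covariate column names,
#'   assembled in the given order.
#' @param family outcome family.
#' @param constraint monotonicity constraint.
#' @param augment_points explicit augmentation points, or `NULL`.
#' @param augment_step grid step; augmentation points are placed at this step
#'   across the observed predictor range (ignored when `augment_points` is
#'   given).
#' @param prior optional `hpr_prior` overriding the data-driven defaults.
#' @param sampler an `hpr_sampler_config`.
#' @param outdir output directory (created if missing).
#' @return List of class `hpr_run_config`.
#' @export
run_config <- function(input, outcome = "y", predictor = "x",
                       covariates = NULL,
                       family = c("gaussian", "bernoulli", "poisson"),
                       constraint = c("none", "increasing", "decreasing"),
                       augment_points = NULL, augment_step = NULL,
                       prior = NULL, sampler = sampler_config(),
                       outdir = ".") {
  family <- match.arg(family)
  constraint <- match.arg(constraint)
  if (!is.null(augment_step) && !(augment_step > 0))
    stop("'augment_step' must be positive", call. = FALSE)
  structure(list(input = input, outcome = outcome, predictor = predictor,
                 covariates = covariates, family = family,
                 constraint = constraint, augment_points = augment_points,
                 augment_step = augment_step, prior = prior, sampler = sampler,
                 outdir = outdir),
            class = "hpr_run_config")
}

#' Read and validate a CSV dataset
#'
#' Checks that the configured columns exist and are numeric, applies the
#' family-specific outcome checks (Bernoulli in \{0, 1\}, Poisson
#' nonnegative integers), and drops rows with a missing outcome, predictor
#' or covariate with a counted warning.
#'
#' @param path CSV file path (header required).
#' @param config an `hpr_run_config` (its `input` field is ignored in favor
#'   of `path`).
#' @return An `hpr_data` object.
#' @export
read_dataset <- function(path, config) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("input file has no rows: ", path, call. = FALSE)
  needed <- c(config$outcome, config$predictor, config$covariates)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in needed) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  keep <- stats::complete.cases(df[, needed, drop = FALSE])
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows remain", call. = FALSE)
  Z <- if (length(config$covariates)) {
    as.matrix(df[, config$covariates, drop = FALSE])
  }
  hpr_data(df[[config$outcome]], df[[config$predictor]], Z = Z,
           family = config$family)
}

#' Fit a model from a run configuration and write outputs
#'
#' Reads the dataset, resolves the augmentation grid, fits the model, and
#' writes to the output directory: `summary.csv` (one row per gridpoint:
#' `t`, `is_observed`, `point`, `lower`, `upper`), `coefficients.csv` when
#' covariates are present (scaled and original units), `diagnostics.json`,
#' and `run_log.json` echoing the seed, package version and configuration so
#' the run can be reproduced.
#'
#' @param config an `hpr_run_config`.
#' @return Invisibly, a list with the fit, summary and file paths.
#' @export
run_fit <- function(config) {
  if (!inherits(config, "hpr_run_config"))
    stop("'config' must come from run_config()", call. = FALSE)
  data <- read_dataset(config$input, config)
  x_aug <- config$augment_points
  if (is.null(x_aug) && !is.null(config$augment_step)) {
    rng <- range(data$x)
    x_aug <- seq(rng[1], rng[2], by = config$augment_step)
  }
  fit <- fit_hpr(data, x_aug = x_aug, prior = config$prior,
                 constraint = config$constraint, sampler = config$sampler)
  summ <- summarize_posterior(fit)
  diag <- diagnostics_report(fit)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(summary = file.path(config$outdir, "summary.csv"),
                diagnostics = file.path(config$outdir, "diagnostics.json"),
                log = file.path(config$outdir, "run_log.json"))
  utils::write.csv(summ, paths$summary, row.names = FALSE)
  if (fit$p > 0L) {
    paths$coefficients <- file.path(config$outdir, "coefficients.csv")
    utils::write.csv(summarize_coefficients(fit), paths$coefficients,
                     row.names = FALSE)
  }
  jsonlite::write_json(unclass(diag), paths$diagnostics, auto_unbox = TRUE,
                       digits = NA)
  log <- list(
    seed = config$sampler$seed,
    package_version = as.character(utils::packageVersion("hproc")),
    r_version = R.version.string,
    config = list(input = config$input, outcome = config$outcome,
                  predictor = config$predictor,
                  covariates = config$covariates, family = config$family,
                  constraint = config$constraint,
                  augment_points = x_aug,
                  augment_step = config$augment_step,
                  prior = if (!is.null(fit$prior)) unclass(fit$prior),
                  sampler = unclass(config$sampler)))
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(fit = fit, summary = summ, diagnostics = diag, paths = paths))
}

#' Run a simulation study from a configuration list and write a tidy CSV
#'
#' Thin wrapper over [run_simulation_study()]: takes a plain list (e.g.
#' parsed from YAML) with fields `scenario`, `family`, `replicates`,
#' optional `n`, `sigma`, `augment_step`, `grid_type`, `seed`, sampler
#' settings (`chains`, `warmup`, `sampling`), and `output` (CSV path).
#'
#' @param config named list of study settings.
#' @return Invisibly, the `hpr_study` object; the tidy per-replicate results
#'   are written to `config$output`.
#' @export
run_study <- function(config) {
  spec <- scenario_spec(config$scenario,
                        n = config$n %||% 100L,
                        sigma = config$sigma)
  sampler <- sampler_config(chains = config$chains %||% 4L,
                            warmup = config$warmup %||% 1000L,
                            sampling = config$sampling %||% 2000L)
  study <- run_simulation_study(
    spec, family = config$family %||% "gaussian",
    replicates = config$replicates %||% 10L, sampler = sampler,
    augment_step = config$augment_step,
    grid_type = config$grid_type %||% "even",
    seed = config$seed %||% 1L)
  out <- config$output %||% "study_results.csv"
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$results, out, row.names = FALSE)
  invisible(study)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
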