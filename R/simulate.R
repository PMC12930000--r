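#' Benchmark truth functions
#'
#' Four data-generating associations on the domain [0, 10], covering the
#' regimes a step-function prior should and should not handle well:
#' \describe{
#'   \item{bigstep}{pure step function: 0 on (-Inf, 2], 6 on (2, 5], 1 on
#'     (5, 6], 3 on (6, 8], 10 above 8.}
#'   \item{joinpoint}{piecewise-linear: 1.5x below 2, 16 - 5x on [2, 3),
#'     1 on [3, 6), 10 - x on [6, 9), 5x - 44 at and above 9.}
#'   \item{impulse}{exponential decays restarting at 0, 3 and 7, with the
#'     printed point conventions honored: exactly 0 at x = 0, exp(-x) on
#'     (0, 3), exp(-(x - 3)) on [3, 7), exp(-(x - 7)) at and above 7.}
#'   \item{bounce}{smooth rectified sine |sin(x)|, always in [0, 1].}
#' }
#' The piecewise formulas are total over the real line, so evaluation outside
#' [0, 10] follows the same branch conditions (bigstep is 0 below 2 and 10
#' above 8, etc.).
#'
#' @param name one of `"bigstep"`, `"joinpoint"`, `"impulse"`, `"bounce"`.
#' @param x numeric evaluation points.
#' @return Numeric vector `f(x)`.
#' @export
true_function <- function(name = c("bigstep", "joinpoint", "impulse", "bounce"),
                          x) {
  name <- match.arg(name)
  switch(name,
    bigstep = 0 * (x <= 2) + 6 * (x > 2 & x <= 5) + 1 * (x > 5 & x <= 6) +
      3 * (x > 6 & x <= 8) + 10 * (x > 8),
    joinpoint = (1.5 * x) * (x < 2) + (16 - 5 * x) * (x >= 2 & x < 3) +
      1 * (x >= 3 & x < 6) + (10 - x) * (x >= 6 & x < 9) +
      (5 * x - 44) * (x >= 9),
    impulse = exp(-x) * (x > 0 & x < 3) + exp(-(x - 3)) * (x >= 3 & x < 7) +
      exp(-(x - 7)) * (x >= 7),
    bounce = abs(sin(x)))
}

# gaussian noise sd per scenario
scenario_sigma <- c(bigstep = 0.5, joinpoint = 0.5, impulse = 0.1, bounce = 0.2)

#' Scenario specification for the simulation harness
#'
#' @param name scenario name (see [true_function()]).
#' @param n sample size (default 100 observations).
#' @param sigma Gaussian noise standard deviation; defaults to the
#'   scenario-specific value (0.5 for bigstep and joinpoint, 0.1 for impulse,
#'   0.2 for bounce).
#' @param domain predictor range (default \code{c(0, 10)}).
#' @return List of class `hpr_scenario`.
#' @export
scenario_spec <- function(name = c("bigstep", "joinpoint", "impulse", "bounce"),
                          n = 100L, sigma = NULL, domain = c(0, 10)) {
  name <- match.arg(name)
  if (is.null(sigma)) sigma <- unname(scenario_sigma[name])
  stopifnot(sigma >= 0, n >= 2, length(domain) == 2L, domain[1] < domain[2])
  structure(list(name = name, n = as.integer(n), sigma = sigma,
                 domain = domain),
            class = "hpr_scenario")
}

#' Simulate a dataset from a benchmark scenario
#'
#' For Gaussian outcomes, `y = f(x) + N(0, sigma^2)` noise at an equally
#' spaced grid of `n` points spanning the domain (endpoints included), or at
#' caller-supplied predictor locations `x`.  For Bernoulli and Poisson
#' outcomes the truth is first rescaled affinely to [-2, 2] (using its range
#' over the domain) and mapped through the inverse link to give the outcome
#' mean; this discrete-outcome transform is a declared stand-in and can be
#' replaced via `mean_transform`.
#'
#' @param spec an `hpr_scenario`.
#' @param family outcome family.
#' @param seed integer seed; fully determines the dataset.
#' @param x optional predictor locations overriding the equally spaced grid
#'   (e.g. from [sample_uneven_grid()]).
#' @param mean_transform optional function mapping truth values to the link
#'   scale for discrete families (default: affine rescale to [-2, 2]).
#' @return An `hpr_data` object with attribute `f_true`, the true latent
#'   (link-scale) function at the sampled predictor values.
#' @export
simulate_dataset <- function(spec, family = c("gaussian", "bernoulli", "poisson"),
                             seed = 1L, x = NULL, mean_transform = NULL) {
  family <- match.arg(family)
  if (!inherits(spec, "hpr_scenario")) stop("'spec' must come from scenario_spec()",
                                            call. = FALSE)
  set.seed(seed)
  if (is.null(x)) {
    x <- seq(spec$domain[1], spec$domain[2], length.out = spec$n)
  }
  f <- true_function(spec$name, x)
  if (family == "gaussian") {
    y <- f + stats::rnorm(length(x), sd = spec$sigma)
    f_link <- f
  } else {
    f_link <- if (is.null(mean_transform)) {
      link_scale_truth(spec)(f)
    } else {
      mean_transform(f)
    }
    y <- if (family == "bernoulli") {
      stats::rbinom(length(x), 1L, stats::plogis(f_link))
    } else {
      stats::rpois(length(x), exp(f_link))
    }
  }
  out <- hpr_data(y, x, family = family)
  attr(out, "f_true") <- f_link
  out
}

# affine map of the truth's range over the domain onto [-2, 2]
link_scale_truth <- function(spec) {
  xx <- seq(spec$domain[1], spec$domain[2], length.out = 2001L)
  r <- range(true_function(spec$name, xx))
  if (r[1] == r[2]) return(function(f) rep(0, length(f)))
  function(f) -2 + 4 * (f - r[1]) / (r[2] - r[1])
}

#' Draw unevenly spaced predictor locations
#'
#' `n` independent uniform draws on the open interval `(lo, hi)`, sorted.
#' The endpoints are not forced into the sample, so a subsequent augmentation
#' grid may extrapolate beyond the observed range.
#'
#' @param n number of points (>= 2).
#' @param lo,hi interval bounds, `lo < hi`.
#' @param seed integer seed.
#' @return Sorted numeric vector of length `n`.
#' @export
sample_uneven_grid <- function(n = 100L, lo = 0, hi = 10, seed = 1L) {
  stopifnot(n >= 2, lo < hi)
  set.seed(seed)
  sort(stats::runif(n, lo, hi))
}

#' Pointwise performance metrics
#'
#' Three metrics, each averaged over the supplied points: mean absolute
#' difference between the truth and the point estimate
#' (`mad = mean(|f - fhat|)`), mean credible-interval width
#' (`width = mean(upper - lower)`), and empirical interval coverage
#' (`coverage = mean(lower <= f <= upper)`).
#'
#' @param f_true truth at the evaluation points.
#' @param summary data frame with columns `point`, `lower`, `upper`, aligned
#'   with `f_true` (e.g. rows of [summarize_posterior()]).
#' @param point_set label recorded in the output (`"observed"`,
#'   `"augmented"` or `"all"`).
#' @return One-row data frame of class `hpr_metrics` with `point_set`,
#'   `mad`, `width`, `coverage`.
#' @export
compute_metrics <- function(f_true, summary,
                            point_set = c("all", "observed", "augmented")) {
  point_set <- match.arg(point_set)
  if (length(f_true) != nrow(summary))
    stop("'f_true' length must match the number of summary rows", call. = FALSE)
  out <- data.frame(
    point_set = point_set,
    mad = mean(abs(f_true - summary$point)),
    width = mean(summary$upper - summary$lower),
    coverage = mean(summary$lower <= f_true & f_true <= summary$upper))
  class(out) <- c("hpr_metrics", "data.frame")
  out
}

#' Run a replicate simulation study
#'
#' For each replicate, simulates a dataset from the scenario (even grid or
#' unevenly spaced predictors), fits the model (optionally with an
#' augmentation grid at a fixed step over the domain), summarizes the
#' posterior, and computes the three metrics -- separately at observed and
#' augmented gridpoints when augmentation is used.  Replicate `r` uses seed
#' `seed + r` for both data generation and sampling, so studies are
#' reproducible and resumable per replicate.  A replicate whose fit fails is
#' recorded with `NA` metrics rather than aborting the study.
#'
#' @param spec an `hpr_scenario`.
#' @param family outcome family.
#' @param replicates number of replicates (>= 1).
#' @param sampler an `hpr_sampler_config` (its `seed` field is ignored in
#'   favor of the per-replicate rule).
#' @param augment_step optional grid step; augmentation points are placed at
#'   `seq(domain[1], domain[2], by = augment_step)`.
#' @param grid_type `"even"` (equally spaced observations) or `"uneven"`
#'   (uniform draws on the open domain).
#' @param seed master seed.
#' @param probs credible-band quantile levels.
#' @return List of class `hpr_study`: `results`, a tidy data frame with one
#'   row per replicate and point set (columns scenario, family, replicate,
#'   point_set, mad, width, coverage), and `aggregate`, per-point-set means
#'   with Monte-Carlo standard errors.
#' @export
run_simulation_study <- function(spec, family = "gaussian", replicates = 10L,
                                 sampler = sampler_config(),
                                 augment_step = NULL,
                                 grid_type = c("even", "uneven"),
                                 seed = 1L, probs = c(0.025, 0.975)) {
  grid_type <- match.arg(grid_type)
  stopifnot(replicates >= 1)
  x_aug <- if (!is.null(augment_step)) {
    stopifnot(augment_step > 0)
    seq(spec$domain[1], spec$domain[2], by = augment_step)
  }
  rows <- list()
  for (r in seq_len(replicates)) {
    seed_r <- seed + r
    x <- if (grid_type == "uneven") {
      sample_uneven_grid(spec$n, spec$domain[1], spec$domain[2], seed = seed_r)
    }
    dat <- simulate_dataset(spec, family, seed = seed_r, x = x)
    samp <- sampler
    samp$seed <- seed_r
    rep_rows <- tryCatch({
      fit <- fit_hpr(dat, x_aug = x_aug, sampler = samp)
      summ <- summarize_posterior(fit, probs = probs)
      truth_grid <- truth_on_grid(spec, family, fit$grid$t)
      if (is.null(x_aug)) {
        list(compute_metrics(truth_grid, summ, "all"))
      } else {
        obs <- summ$is_observed
        list(compute_metrics(truth_grid[obs], summ[obs, ], "observed"),
             compute_metrics(truth_grid[!obs], summ[!obs, ], "augmented"))
      }
    }, error = function(e) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      ps <- if (is.null(x_aug)) "all" else c("observed", "augmented")
      lapply(ps, function(s) data.frame(point_set = s, mad = NA_real_,
                                        width = NA_real_, coverage = NA_real_))
    })
    for (rr in rep_rows) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = spec$name, family = family, replicate = r),
        as.data.frame(rr))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  aggregate <- do.call(rbind, lapply(split(results, results$point_set), function(g) {
    data.frame(point_set = g$point_set[1L], replicates = nrow(g),
               mad = mean(g$mad, na.rm = TRUE),
               mad_se = mc_se(g$mad),
               width = mean(g$width, na.rm = TRUE),
               width_se = mc_se(g$width),
               coverage = mean(g$coverage, na.rm = TRUE),
               coverage_se = mc_se(g$coverage))
  }))
  rownames(aggregate) <- NULL
  structure(list(results = results, aggregate = aggregate, scenario = spec,
                 family = family, seed = seed),
            class = "hpr_study")
}

# truth at gridpoints, on the link scale used to generate the data
truth_on_grid <- function(spec, family, t) {
  f <- true_function(spec$name, t)
  if (family == "gaussian") f else link_scale_truth(spec)(f)
}

mc_se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @export
print.hpr_study <- function(x, ...) {
  cat(sprintf("<hpr_study> scenario = %s, family = %s, %d replicates\n",
              x$scenario$name, x$family, max(x$results$replicate)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
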