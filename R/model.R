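#' Default prior configuration
#'
#' Data-driven defaults for the horseshoe process regression priors.  The
#' intercept gets a normal prior centered at the (link-transformed) sample
#' mean of the outcome with scale five times the sample standard deviation for
#' Gaussian outcomes; for discrete outcomes the mean is mapped through the
#' link after clamping (Bernoulli: mean clamped to [0.01, 0.99] before the
#' logit; Poisson: floored at 0.01 before the log) and the scale is 5.  The
#' global-shrinkage half-Cauchy scale is fixed at `c = 0.01`, the residual-sd
#' half-Cauchy scale at `s = 5` (Gaussian only), and the normal prior scale on
#' linear coefficients is 5 per coefficient for continuous outcomes and 2.5
#' for discrete outcomes.
#'
#' @param y outcome vector (on the response scale).
#' @param family outcome family name.
#' @param p number of linear covariates.
#' @return An object of class `hpr_prior`: list with fields `a`, `b`, `c`,
#'   `s`, `d`.
#' @export
default_priors <- function(y, family = c("gaussian", "bernoulli", "poisson"),
                           p = 0L) {
  family <- match.arg(family)
  if (length(y) == 0L) stop("'y' must be nonempty", call. = FALSE)
  if (family == "gaussian") {
    a <- mean(y)
    sdy <- stats::sd(y)
    if (length(y) < 2L || !is.finite(sdy) || sdy == 0) {
      warning("outcome has zero variance; falling back to intercept prior scale 5")
      b <- 5
    } else {
      b <- 5 * sdy
    }
  } else if (family == "bernoulli") {
    a <- stats::qlogis(min(max(mean(y), 0.01), 0.99))
    b <- 5
  } else {
    a <- log(max(mean(y), 0.01))
    b <- 5
  }
  d_scale <- if (family == "gaussian") 5 else 2.5
  hpr_prior(a = a, b = b, c = 0.01, s = 5, d = rep(d_scale, p))
}

#' Assemble a prior configuration
#'
#' @param a intercept prior mean.
#' @param b intercept prior scale (> 0).
#' @param c global-shrinkage half-Cauchy scale (> 0).
#' @param s residual-sd half-Cauchy scale (> 0; used for Gaussian outcomes).
#' @param d per-coefficient normal prior scales (each > 0).
#' @return An object of class `hpr_prior`.
#' @export
hpr_prior <- function(a, b, c = 0.01, s = 5, d = numeric(0)) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  if (!(b > 0) || !(c > 0) || !(s > 0) || any(d <= 0))
    stop("prior scales b, c, s and all d must be positive", call. = FALSE)
  structure(list(a = a, b = b, c = c, s = s, d = as.numeric(d)),
            class = "hpr_prior")
}

#' @export
print.hpr_prior <- function(x, ...) {
  cat(sprintf("<hpr_prior> alpha ~ N(%.4g, %.4g^2), tau ~ C+(0, %g), sigma ~ C+(0, %g)",
              x$a, x$b, x$c, x$s))
  if (length(x$d)) cat(sprintf(", beta scales = [%s]", paste(x$d, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Center and scale a covariate matrix
#'
#' Continuous columns are centered and rescaled to standard deviation 1 when
#' the outcome is Gaussian and 0.5 when it is discrete (Bernoulli/Poisson),
#' so the default coefficient priors are comparably informative across
#' outcome types.  Binary 0/1 dummy columns are centered but not rescaled, so
#' their coefficients remain interpretable per level.  Constant columns are
#' centered only, with a warning.
#'
#' @param Z numeric covariate matrix.
#' @param family outcome family name (controls the target scale).
#' @return List with `Z` (transformed matrix), `center` and `scale` (the
#'   divisor applied per column; 1 for columns left unscaled).  A coefficient
#'   on the transformed scale maps back to original units by dividing by
#'   `scale`.
#' @export
scale_covariates <- function(Z, family = c("gaussian", "bernoulli", "poisson")) {
  family <- match.arg(family)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("'Z' must be finite", call. = FALSE)
  target_sd <- if (family == "gaussian") 1 else 0.5
  p <- ncol(Z)
  center <- colMeans(Z)
  scale <- rep(1, p)
  out <- Z
  for (l in seq_len(p)) {
    col <- Z[, l]
    is_dummy <- all(col %in% c(0, 1))
    sdl <- stats::sd(col)
    if (is_dummy) {
      out[, l] <- col - center[l]
    } else if (!is.finite(sdl) || sdl == 0) {
      warning(sprintf("covariate column %d is constant; centered but not scaled", l))
      out[, l] <- col - center[l]
    } else {
      scale[l] <- sdl / target_sd
      out[, l] <- (col - center[l]) / scale[l]
    }
  }
  names(center) <- names(scale) <- colnames(Z)
  list(Z = out, center = center, scale = scale)
}

#' Map raw (non-centered) parameters to model space
#'
#' The sampler works on primitive parameters with fixed priors; model-space
#' parameters are deterministic transforms chosen so the implied marginals
#' are the stated ones: `tau = c * |tau1| * sqrt(tau2)` is half-Cauchy with
#' scale `c` when `tau1 ~ N(0,1)` and `tau2 ~ InvGamma(1/2, 1/2)` (and
#' analogously for the local shrinkage `lam` and the residual sd `sigma`).
#' Increments are `h_k = gamma_k * tau * lam_k * sqrt(t_k - t_{k-1})`, so that
#' conditional on the shrinkage parameters `h_k` is centered normal with
#' variance `tau^2 lam_k^2 (t_k - t_{k-1})`.  The latent function is the
#' intercept plus the cumulative sum of the increments; under a monotone
#' constraint the absolute increments are summed (negated for decreasing).
#'
#' @param raw list of raw parameters: `alpha_raw`, `tau1`, `tau2` (> 0),
#'   `lambda1`, `lambda2` (> 0, both length `m - 1`), `gamma` (length
#'   `m - 1`), optionally `sigma1`, `sigma2` (> 0) and `beta_raw`.
#' @param prior an `hpr_prior`.
#' @param grid an `hpr_grid`.
#' @param constraint `"none"`, `"increasing"` or `"decreasing"`.
#' @return List of class `hpr_params`: `alpha`, `tau`, `lam`, `h` (with
#'   `h[1]` identically 0 represented by the vector starting at k = 2),
#'   `f_grid` (latent function at every gridpoint), `sigma` (or `NULL`),
#'   `beta`.
#' @export
transform_raw <- function(raw, prior, grid,
                          constraint = c("none", "increasing", "decreasing")) {
  constraint <- match.arg(constraint)
  m <- length(grid$t)
  M <- m - 1L
  stopifnot(length(raw$lambda1) == M, length(raw$lambda2) == M,
            length(raw$gamma) == M)
  if (!(is.null(raw$tau2) || raw$tau2 > 0) || any(raw$lambda2 <= 0))
    stop("tau2 and lambda2 must be positive", call. = FALSE)
  alpha <- prior$a + prior$b * raw$alpha_raw
  tau <- prior$c * abs(raw$tau1) * sqrt(raw$tau2)
  lam <- abs(raw$lambda1) * sqrt(raw$lambda2)
  h <- raw$gamma * tau * lam * sqrt(grid$delta)
  inc <- switch(constraint, none = h, increasing = abs(h), decreasing = -abs(h))
  f_grid <- alpha + c(0, cumsum(inc))
  sigma <- NULL
  if (!is.null(raw$sigma1)) {
    if (!(raw$sigma2 > 0)) stop("sigma2 must be positive", call. = FALSE)
    sigma <- prior$s * abs(raw$sigma1) * sqrt(raw$sigma2)
  }
  beta <- if (is.null(raw$beta_raw)) numeric(0) else prior$d * raw$beta_raw
  structure(list(alpha = alpha, tau = tau, lam = lam, h = h, f_grid = f_grid,
                 sigma = sigma, beta = beta),
            class = "hpr_params")
}

#' Per-observation linear predictor
#'
#' `eta_i = f_grid[obs_index[i]] + beta . z_i`, the latent function value at
#' the observation's gridpoint plus the linear covariate contribution.
#'
#' @param tp an `hpr_params` object (see [transform_raw()]).
#' @param grid an `hpr_grid`.
#' @param Z optional covariate matrix (rows = observations).
#' @return Numeric vector of linear predictors, one per observation.
#' @export
latent_mean <- function(tp, grid, Z = NULL) {
  eta <- tp$f_grid[grid$obs_index]
  if (!is.null(Z) && length(tp$beta)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(grid$obs_index))
      stop("'Z' must have one row per observation", call. = FALSE)
    if (ncol(Z) != length(tp$beta))
      stop("'Z' column count must match length of beta", call. = FALSE)
    eta <- eta + as.vector(Z %*% tp$beta)
  }
  eta
}

# log density of InvGamma(1/2, 1/2) at v
dinvgamma_half_log <- function(v) {
  0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(v) - 0.5 / v
}

#' Joint log posterior density of the raw parameters
#'
#' Evaluates, up to no omitted terms (all normalizing constants included),
#' the sum of the raw-parameter log priors -- standard normal for the
#' unconstrained components, InvGamma(1/2, 1/2) for the positive components
#' -- and the family log likelihood of the outcome given the linear
#' predictor.  Only gridpoints carrying observations enter the likelihood;
#' augmentation gridpoints contribute prior terms only, which is exactly the
#' marginalization that lets the fit interpolate without a prior on the
#' unobserved outcomes.
#'
#' This R implementation is the reference definition of the model density;
#' the compiled sampler targets the same function (plus the log-Jacobian of
#' its internal log-scale representation of the positive parameters).
#'
#' @param raw raw parameter list (see [transform_raw()]).
#' @param data an `hpr_data` object.
#' @param grid an `hpr_grid` built from `data$x` (plus any augmentation).
#' @param prior an `hpr_prior`.
#' @param constraint `"none"`, `"increasing"` or `"decreasing"`.
#' @return Scalar log density.
#' @export
log_posterior <- function(raw, data, grid,
                          prior, constraint = c("none", "increasing", "decreasing")) {
  constraint <- match.arg(constraint)
  check_family_outcome(data$y, data$family)
  lp <- stats::dnorm(raw$alpha_raw, log = TRUE) +
    stats::dnorm(raw$tau1, log = TRUE) +
    dinvgamma_half_log(raw$tau2) +
    sum(stats::dnorm(raw$lambda1, log = TRUE)) +
    sum(dinvgamma_half_log(raw$lambda2)) +
    sum(stats::dnorm(raw$gamma, log = TRUE))
  if (data$family == "gaussian") {
    lp <- lp + stats::dnorm(raw$sigma1, log = TRUE) +
      dinvgamma_half_log(raw$sigma2)
  }
  if (!is.null(raw$beta_raw)) {
    lp <- lp + sum(stats::dnorm(raw$beta_raw, log = TRUE))
  }
  tp <- transform_raw(raw, prior, grid, constraint)
  eta <- latent_mean(tp, grid, data$Z)
  ll <- switch(data$family,
    gaussian  = sum(stats::dnorm(data$y, mean = eta, sd = tp$sigma, log = TRUE)),
    bernoulli = sum(stats::dbinom(data$y, size = 1, prob = stats::plogis(eta),
                                  log = TRUE)),
    poisson   = sum(stats::dpois(data$y, lambda = exp(eta), log = TRUE)))
  lp + ll
}
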