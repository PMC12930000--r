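#' Sampler configuration
#'
#' Defaults follow common practice for Hamiltonian Monte Carlo on horseshoe
#' posteriors: four chains with 1000 warmup and 2000 retained iterations each
#' (8000 retained draws total, no thinning), and a high acceptance target
#' (0.95) to reduce divergences in the funnel-like geometry the shrinkage
#' parameters induce.
#'
#' @param chains number of chains (>= 1).
#' @param warmup warmup (adaptation) iterations per chain.
#' @param sampling retained sampling iterations per chain.
#' @param seed integer seed; together with the data and configuration it
#'   fully determines the draws.
#' @param adapt_target step-size adaptation acceptance target in (0, 1).
#' @param max_treedepth maximum trajectory tree depth.
#' @return List of class `hpr_sampler_config`.
#' @export
sampler_config <- function(chains = 4L, warmup = 1000L, sampling = 2000L,
                           seed = 1L, adapt_target = 0.95,
                           max_treedepth = 10L) {
  stopifnot(chains >= 1, warmup >= 1, sampling >= 1,
            adapt_target > 0, adapt_target < 1, max_treedepth >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed),
                 adapt_target = adapt_target,
                 max_treedepth = as.integer(max_treedepth)),
            class = "hpr_sampler_config")
}

# dimension of the unconstrained parameter vector
param_dim <- function(m, family, p) {
  3L + 3L * (m - 1L) + (if (family == "gaussian") 2L else 0L) + p
}

# model description handed to the compiled sampler
model_spec_list <- function(data, grid, prior, constraint, Z) {
  n <- length(data$y)
  if (is.null(Z)) Z <- matrix(0, n, 0)
  list(y = data$y, obs_index = as.integer(grid$obs_index), delta = grid$delta,
       Z = Z, family = family_code(data$family),
       constraint = constraint_code(constraint),
       a = prior$a, b = prior$b, c = prior$c, s = prior$s,
       d = prior$d)
}

# unconstrained vector -> natural-scale raw parameter list
vector_to_raw <- function(q, m, family, p) {
  M <- m - 1L
  raw <- list(alpha_raw = q[1L], tau1 = q[2L], tau2 = exp(q[3L]),
              lambda1 = q[3L + seq_len(M)],
              lambda2 = exp(q[3L + M + seq_len(M)]),
              gamma = q[3L + 2L * M + seq_len(M)])
  off <- 3L + 3L * M
  if (family == "gaussian") {
    raw$sigma1 <- q[off + 1L]
    raw$sigma2 <- exp(q[off + 2L])
    off <- off + 2L
  }
  if (p > 0L) raw$beta_raw <- q[off + seq_len(p)]
  raw
}

# vectorized transform of an S x D draw matrix to model space
transform_draw_matrix <- function(Q, prior, grid, constraint, family, p) {
  S <- nrow(Q)
  m <- length(grid$t)
  M <- m - 1L
  alpha <- prior$a + prior$b * Q[, 1L]
  tau <- prior$c * abs(Q[, 2L]) * exp(0.5 * Q[, 3L])
  if (M > 0L) {
    lam <- abs(Q[, 3L + seq_len(M), drop = FALSE]) *
      exp(0.5 * Q[, 3L + M + seq_len(M), drop = FALSE])
    h <- Q[, 3L + 2L * M + seq_len(M), drop = FALSE] * lam * tau
    h <- sweep(h, 2L, sqrt(grid$delta), `*`)
    inc <- switch(constraint, none = h, increasing = abs(h), decreasing = -abs(h))
    # rowwise cumulative sums; apply() would drop dimensions when M == 1
    cs <- if (M == 1L) inc else t(apply(inc, 1L, cumsum))
    f <- alpha + cbind(0, cs)
  } else {
    lam <- h <- matrix(numeric(0), S, 0L)
    f <- matrix(alpha, S, 1L)
  }
  off <- 3L + 3L * M
  sigma <- NULL
  if (family == "gaussian") {
    sigma <- prior$s * abs(Q[, off + 1L]) * exp(0.5 * Q[, off + 2L])
    off <- off + 2L
  }
  beta <- if (p > 0L) {
    sweep(Q[, off + seq_len(p), drop = FALSE], 2L, prior$d, `*`)
  } else {
    matrix(numeric(0), S, 0L)
  }
  list(alpha = alpha, tau = tau, lam = lam, h = h, f = f, sigma = sigma,
       beta = beta)
}

#' Fit a horseshoe process regression
#'
#' Builds the evaluation grid from the observed predictor values and any
#' augmentation points, assembles priors (data-driven defaults unless
#' supplied), and samples the posterior with the package's No-U-Turn sampler
#' over the non-centered parameterization.  Every gridpoint -- observed or
#' augmented -- carries its own local shrinkage and increment parameters, so
#' the returned draws of the latent function cover augmentation points too.
#'
#' Covariates, when present, are centered/scaled via [scale_covariates()]
#' before fitting; the transform record is stored so coefficients can be
#' reported in original units.
#'
#' @param data an `hpr_data` object (see [hpr_data()]).
#' @param x_aug optional numeric vector of augmentation points.
#' @param prior an `hpr_prior`, or `NULL` for [default_priors()].
#' @param constraint `"none"`, `"increasing"` or `"decreasing"` monotonicity.
#' @param sampler an `hpr_sampler_config`.
#' @param scale_Z whether to center/scale covariates before fitting.
#' @return An object of class `hpr_fit` holding per-draw model-space
#'   parameters (`draws$f` is retained-draws x gridpoints), chain indexing,
#'   per-iteration divergence and treedepth flags, per-parameter split R-hat
#'   and effective sample size, and the grid, prior and configuration used.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- seq(0, 10, length.out = 40)
#' y <- ifelse(x > 5, 3, 0) + rnorm(40, sd = 0.5)
#' fit <- fit_hpr(hpr_data(y, x),
#'                sampler = sampler_config(chains = 2, warmup = 300,
#'                                         sampling = 300))
#' head(summarize_posterior(fit))
#' }
#' @export
fit_hpr <- function(data, x_aug = NULL, prior = NULL,
                    constraint = c("none", "increasing", "decreasing"),
                    sampler = sampler_config(), scale_Z = TRUE) {
  if (!inherits(data, "hpr_data")) stop("'data' must be an hpr_data object",
                                        call. = FALSE)
  constraint <- match.arg(constraint)
  if (!inherits(sampler, "hpr_sampler_config"))
    stop("'sampler' must come from sampler_config()", call. = FALSE)
  grid <- build_grid(data$x, x_aug)
  p <- if (is.null(data$Z)) 0L else ncol(data$Z)
  if (is.null(prior)) prior <- default_priors(data$y, data$family, p)
  if (!inherits(prior, "hpr_prior")) stop("'prior' must be an hpr_prior",
                                          call. = FALSE)
  if (length(prior$d) != p)
    stop("length of prior$d must equal the number of covariates", call. = FALSE)
  Z <- data$Z
  scale_record <- NULL
  if (p > 0L && scale_Z) {
    scale_record <- scale_covariates(Z, data$family)
    Z <- scale_record$Z
  }
  spec <- model_spec_list(data, grid, prior, constraint, Z)
  m <- length(grid$t)
  D <- param_dim(m, data$family, p)

  set.seed(sampler$seed)
  chain_res <- vector("list", sampler$chains)
  for (ch in seq_len(sampler$chains)) {
    res <- NULL
    for (attempt in 1:4) {   # bounded retry on degenerate initial points
      q0 <- stats::runif(D, -2, 2)
      res <- tryCatch(
        .hpr_nuts(spec, q0, sampler$warmup, sampler$sampling,
                  sampler$adapt_target, sampler$max_treedepth),
        error = function(e) {
          if (attempt == 4) stop("sampler failed to initialize: ",
                                 conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(res)) break
    }
    chain_res[[ch]] <- res
  }

  Q <- do.call(rbind, lapply(chain_res, `[[`, "draws"))
  tp <- transform_draw_matrix(Q, prior, grid, constraint, data$family, p)
  chain <- rep(seq_len(sampler$chains), each = sampler$sampling)
  divergent <- unlist(lapply(chain_res, `[[`, "divergent"))
  treedepth_hit <- unlist(lapply(chain_res, `[[`, "treedepth_hit"))

  fit <- structure(list(
    draws = tp,
    lp = unlist(lapply(chain_res, `[[`, "lp")),
    chain = chain,
    divergent = divergent,
    treedepth_hit = treedepth_hit,
    accept_stat = unlist(lapply(chain_res, `[[`, "accept_stat")),
    stepsize = vapply(chain_res, `[[`, numeric(1), "stepsize"),
    grid = grid,
    prior = prior,
    family = data$family,
    constraint = constraint,
    sampler = sampler,
    n_obs = length(data$y),
    p = p,
    scale_record = scale_record),
    class = "hpr_fit")
  fit$monitor <- monitor_fit(fit)
  fit
}

# per-parameter split R-hat and effective sample size for the main
# model-space quantities (latent function, shrinkage, sd, coefficients)
monitor_fit <- function(fit) {
  d <- fit$draws
  mats <- cbind(alpha = d$alpha, tau = d$tau, sigma = d$sigma, lp = fit$lp)
  if (ncol(d$f)) {
    fm <- d$f
    colnames(fm) <- paste0("f[", seq_len(ncol(fm)), "]")
    mats <- cbind(mats, fm)
  }
  if (ncol(d$beta)) {
    bm <- d$beta
    colnames(bm) <- paste0("beta[", seq_len(ncol(bm)), "]")
    mats <- cbind(mats, bm)
  }
  nchain <- fit$sampler$chains
  niter <- fit$sampler$sampling
  out <- data.frame(param = colnames(mats), rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mats))) {
    xm <- matrix(mats[, j], niter, nchain)
    out$rhat[j] <- split_rhat(xm)
    out$ess[j] <- ess_basic(xm)
  }
  out
}

# split R-hat on an iterations x chains matrix; NA for a single unsplittable
# chain is impossible (splitting always yields >= 2 sequences), but constant
# draws give NaN which we report as NA
split_rhat <- function(x) {
  xs <- split_chains(x)
  n <- nrow(xs)
  mu <- colMeans(xs)
  W <- mean(apply(xs, 2L, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

# biased autocovariance via FFT
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / nfft
  ac[seq_len(n)] / n
}

# effective sample size across split chains (Geyer initial monotone sequence)
ess_basic <- function(x) {
  xs <- split_chains(x)
  n <- nrow(xs)
  nc <- ncol(xs)
  if (n < 4) return(NA_real_)
  acov <- apply(xs, 2L, autocov_fft)
  chain_mean <- colMeans(xs)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (nc > 1) var_plus <- var_plus + stats::var(chain_mean)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- 0
  prev_pair <- Inf
  t <- 1L
  while (t + 1L <= n) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + pair
    prev_pair <- pair
    t <- t + 2L
  }
  tau <- max(2 * tau - 1, 1 / log10(n * nc))
  min(n * nc / tau, n * nc * log10(n * nc))
}

#' Summarize the posterior of the latent function per gridpoint
#'
#' @param fit an `hpr_fit`.
#' @param probs length-2 increasing vector of quantile levels in (0, 1) for
#'   the credible band; default the central 95\% interval.
#' @param point `"mean"` (default) or `"median"` posterior point estimate.
#' @return Data frame with one row per gridpoint: `t`, `is_observed`,
#'   `point`, `lower`, `upper`.  Quantiles use the default empirical quantile
#'   rule (type 7).
#' @export
summarize_posterior <- function(fit, probs = c(0.025, 0.975),
                                point = c("mean", "median")) {
  if (!inherits(fit, "hpr_fit")) stop("'fit' must be an hpr_fit", call. = FALSE)
  point <- match.arg(point)
  if (length(probs) != 2L || probs[1] >= probs[2] ||
      any(probs <= 0) || any(probs >= 1))
    stop("'probs' must be two increasing values in (0, 1)", call. = FALSE)
  f <- fit$draws$f
  if (is.null(f) || nrow(f) == 0L) stop("empty fit", call. = FALSE)
  est <- if (point == "mean") colMeans(f) else apply(f, 2L, stats::median)
  qs <- apply(f, 2L, stats::quantile, probs = probs, names = FALSE)
  data.frame(t = fit$grid$t, is_observed = fit$grid$is_observed,
             point = est, lower = qs[1L, ], upper = qs[2L, ])
}

#' Summarize linear-covariate coefficients
#'
#' Reports posterior mean and central credible interval for each coefficient
#' on the scaled fitting space and, when a scaling record is present, back on
#' the original covariate units (scaled estimate divided by the stored column
#' divisor).
#'
#' @param fit an `hpr_fit` with covariates.
#' @param probs credible-interval quantile levels.
#' @return Data frame with one row per coefficient.
#' @export
summarize_coefficients <- function(fit, probs = c(0.025, 0.975)) {
  if (fit$p == 0L) stop("fit has no covariates", call. = FALSE)
  b <- fit$draws$beta
  est <- colMeans(b)
  qs <- apply(b, 2L, stats::quantile, probs = probs, names = FALSE)
  scale <- if (is.null(fit$scale_record)) rep(1, fit$p) else fit$scale_record$scale
  data.frame(coefficient = seq_len(fit$p),
             point_scaled = est, lower_scaled = qs[1L, ], upper_scaled = qs[2L, ],
             point = est / scale, lower = qs[1L, ] / scale,
             upper = qs[2L, ] / scale)
}

#' Sampler diagnostics report
#'
#' Fractions are over retained (post-warmup) iterations pooled across chains.
#' The verdict warns when the divergence fraction reaches the threshold
#' (default 5\%, the usual rule of thumb below which sporadic divergences are
#' tolerable for horseshoe-type posteriors) or when the worst split R-hat
#' exceeds its cutoff.  With a single chain R-hat across chains is still
#' computed from the split halves; effective sample size is always computed.
#'
#' @param fit an `hpr_fit`.
#' @param divergence_threshold warn at or above this divergence fraction.
#' @param rhat_threshold warn above this split R-hat.
#' @return List of class `hpr_diagnostics` with `divergence_frac`,
#'   `treedepth_frac`, `max_rhat`, `min_ess`, `verdict`.
#' @export
diagnostics_report <- function(fit, divergence_threshold = 0.05,
                               rhat_threshold = 1.01) {
  if (!inherits(fit, "hpr_fit")) stop("'fit' must be an hpr_fit", call. = FALSE)
  div_frac <- mean(fit$divergent)
  td_frac <- mean(fit$treedepth_hit)
  max_rhat <- suppressWarnings(max(fit$monitor$rhat, na.rm = TRUE))
  if (!is.finite(max_rhat)) max_rhat <- NA_real_
  min_ess <- suppressWarnings(min(fit$monitor$ess, na.rm = TRUE))
  if (!is.finite(min_ess)) min_ess <- NA_real_
  verdict <- if (div_frac >= divergence_threshold ||
                 (!is.na(max_rhat) && max_rhat > rhat_threshold)) "warn" else "ok"
  structure(list(divergence_frac = div_frac, treedepth_frac = td_frac,
                 max_rhat = max_rhat, min_ess = min_ess, verdict = verdict),
            class = "hpr_diagnostics")
}

#' @export
print.hpr_diagnostics <- function(x, ...) {
  cat(sprintf("<hpr_diagnostics> divergences: %.2f%%  treedepth hits: %.2f%%  max Rhat: %s  min ESS: %s  [%s]\n",
              100 * x$divergence_frac, 100 * x$treedepth_frac,
              ifelse(is.na(x$max_rhat), "NA", sprintf("%.3f", x$max_rhat)),
              ifelse(is.na(x$min_ess), "NA", sprintf("%.0f", x$min_ess)),
              x$verdict))
  invisible(x)
}

#' @export
print.hpr_fit <- function(x, ...) {
  cat(sprintf("<hpr_fit> family = %s, constraint = %s\n", x$family, x$constraint))
  cat(sprintf("  %d observations on %d gridpoints (%d augmented), %d covariates\n",
              x$n_obs, length(x$grid$t), sum(!x$grid$is_observed), x$p))
  cat(sprintf("  %d chains x %d draws = %d retained draws; %d divergences (%.2f%%)\n",
              x$sampler$chains, x$sampler$sampling, length(x$chain),
              sum(x$divergent), 100 * mean(x$divergent)))
  invisible(x)
}
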