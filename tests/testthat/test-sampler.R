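# the compiled density/gradient is checked against the R-side reference
# density and against numerical differentiation; the sampler against its
# stated contracts (draw counts, determinism, contraction, constraints)

test_that("compiled log density equals the reference density plus log-Jacobian", {
  set.seed(21)
  cases <- expand.grid(family = c("gaussian", "bernoulli", "poisson"),
                       constraint = c("none", "increasing", "decreasing"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    fam <- cases$family[i]
    con <- cases$constraint[i]
    n <- 8
    x <- sort(runif(n, 0, 10))
    y <- switch(fam, gaussian = rnorm(n), bernoulli = rbinom(n, 1, 0.5),
                poisson = rpois(n, 3))
    Z <- matrix(rnorm(n), n, 1)
    dat <- hpr_data(y, x, Z = Z, family = fam)
    g <- build_grid(x, x_aug = c(1.23, 8.7))
    pr <- hpr_prior(a = 0.2, b = 1.5, c = 0.01, s = 5, d = 2.5)
    raw <- random_raw(length(g$delta), family = fam, p = 1)
    q <- raw_to_vector(raw)
    spec <- model_spec_for(dat, g, pr, con)
    cpp <- hproc:::.hpr_lp_grad(spec, q)
    jac <- log(raw$tau2) + sum(log(raw$lambda2)) +
      if (fam == "gaussian") log(raw$sigma2) else 0
    expect_equal(cpp$lp, log_posterior(raw, dat, g, pr, con) + jac,
                 tolerance = 1e-10, info = paste(fam, con))
  }
})

test_that("compiled gradient matches central finite differences", {
  set.seed(22)
  for (fam in c("gaussian", "bernoulli", "poisson")) {
    n <- 10
    x <- sort(runif(n, 0, 10))
    y <- switch(fam, gaussian = rnorm(n), bernoulli = rbinom(n, 1, 0.5),
                poisson = rpois(n, 2))
    dat <- hpr_data(y, x, family = fam)
    g <- build_grid(x)
    pr <- hpr_prior(a = 0, b = 2, c = 0.01, s = 5)
    spec <- model_spec_for(dat, g, pr, "increasing")
    D <- hproc:::param_dim(length(g$t), fam, 0L)
    q <- rnorm(D, 0, 0.5)
    cpp <- hproc:::.hpr_lp_grad(spec, q)
    num <- vapply(seq_len(D), function(j) {
      qp <- q; qm <- q
      qp[j] <- q[j] + 1e-6; qm[j] <- q[j] - 1e-6
      (hproc:::.hpr_lp_grad(spec, qp)$lp - hproc:::.hpr_lp_grad(spec, qm)$lp) / 2e-6
    }, numeric(1))
    expect_equal(cpp$grad, num, tolerance = 1e-4, info = fam)
  }
})

test_that("vectorized draw transform agrees with the scalar transform", {
  set.seed(25)
  pr <- hpr_prior(a = 0.5, b = 2, c = 0.01, s = 5, d = c(5, 2.5))
  for (M in c(1L, 2L, 7L)) {            # including the single-increment grid
    g <- build_grid(seq(0, 3, length.out = M + 1L))
    for (con in c("none", "increasing", "decreasing")) {
      raw <- random_raw(M, family = "gaussian", p = 2L)
      Q <- rbind(raw_to_vector(raw), raw_to_vector(raw))
      tpv <- hproc:::transform_draw_matrix(Q, pr, g, con, "gaussian", 2L)
      tps <- transform_raw(raw, pr, g, con)
      expect_equal(unname(tpv$f[1L, ]), tps$f_grid)
      expect_equal(unname(tpv$h[1L, ]), tps$h)
      expect_equal(tpv$alpha[1L], tps$alpha)
      expect_equal(tpv$tau[1L], tps$tau)
      expect_equal(tpv$sigma[1L], tps$sigma)
      expect_equal(unname(tpv$beta[1L, ]), tps$beta)
    }
  }
})

test_that("a two-gridpoint fit runs and summarizes", {
  dat <- hpr_data(c(0.1, -0.2, 0.4, 0.5), c(1, 1, 2, 2), family = "gaussian")
  fit <- fit_hpr(dat, sampler = quick_sampler(seed = 6, chains = 1L,
                                              warmup = 150L, sampling = 100L))
  s <- summarize_posterior(fit)
  expect_equal(nrow(s), 2L)
  expect_true(all(s$lower <= s$upper))
})

test_that("default configuration retains chains x sampling draws", {
  cfg <- sampler_config()
  expect_equal(cfg$chains * cfg$sampling, 8000L)
  set.seed(31)
  dat <- hpr_data(rnorm(6), 1:6, family = "gaussian")
  fit <- fit_hpr(dat, sampler = quick_sampler(seed = 31, chains = 3L,
                                              warmup = 100L, sampling = 50L))
  expect_equal(length(fit$draws$alpha), 150L)
  expect_equal(dim(fit$draws$f), c(150L, 6L))
  expect_equal(table(fit$chain), table(rep(1:3, each = 50)))
})

test_that("a single-observation fit runs and summarizes", {
  dat <- hpr_data(0.5, 3, family = "gaussian")
  # one observation: the default intercept-scale rule falls back with a warning
  expect_warning(
    fit <- fit_hpr(dat, sampler = quick_sampler(seed = 5, chains = 1L,
                                                warmup = 150L, sampling = 100L)),
    "zero variance")
  s <- summarize_posterior(fit)
  expect_equal(nrow(s), 1L)
  expect_true(s$lower <= s$upper)
})

test_that("identical seed and data reproduce the fit exactly", {
  set.seed(41)
  x <- seq(0, 10, length.out = 25)
  y <- true_function("bigstep", x) + rnorm(25, sd = 0.5)
  dat <- hpr_data(y, x, family = "gaussian")
  cfg <- quick_sampler(seed = 99, chains = 2L, warmup = 150L, sampling = 100L)
  f1 <- fit_hpr(dat, sampler = cfg)
  f2 <- fit_hpr(dat, sampler = cfg)
  expect_identical(f1$draws$f, f2$draws$f)
  expect_identical(f1$divergent, f2$divergent)
  expect_identical(summarize_posterior(f1), summarize_posterior(f2))
  # a different seed gives different draws
  cfg2 <- quick_sampler(seed = 100, chains = 2L, warmup = 150L, sampling = 100L)
  f3 <- fit_hpr(dat, sampler = cfg2)
  expect_false(identical(f1$draws$f, f3$draws$f))
})

test_that("posterior bands cover and contract on near-constant data", {
  # exactly constant data: the residual sd collapses toward zero and the
  # bands degenerate onto the truth, so coverage is checked to numerical
  # tolerance
  dat0 <- hpr_data(rep(5, 20), seq(0, 10, length.out = 20), family = "gaussian")
  fit0 <- fit_hpr(dat0, prior = hpr_prior(a = 5, b = 5, c = 0.01, s = 5),
                  sampler = quick_sampler(seed = 20, chains = 2L,
                                          warmup = 250L, sampling = 250L))
  s0 <- summarize_posterior(fit0)
  expect_true(all(s0$lower <= 5 + 1e-8 & 5 <= s0$upper + 1e-8))
  expect_lt(mean(s0$upper - s0$lower), 0.1)

  # contraction: with fixed small noise around the constant, bands narrow as
  # the sample grows
  widths <- sapply(c(10, 100), function(n) {
    set.seed(n)
    y <- 5 + rnorm(n, sd = 0.2)
    dat <- hpr_data(y, seq(0, 10, length.out = n), family = "gaussian")
    fit <- fit_hpr(dat, sampler = quick_sampler(seed = n, chains = 2L,
                                                warmup = 250L, sampling = 250L))
    s <- summarize_posterior(fit)
    expect_gt(mean(s$lower <= 5 & 5 <= s$upper), 0.9)
    mean(s$upper - s$lower)
  })
  expect_lt(widths[2], widths[1])
})

test_that("every retained draw of a monotone fit respects the constraint", {
  set.seed(51)
  x <- seq(0, 10, length.out = 30)
  y <- true_function("bigstep", x) + rnorm(30, sd = 0.5)   # roughly increasing
  dat <- hpr_data(y, x, family = "gaussian")
  fit <- fit_hpr(dat, constraint = "increasing",
                 sampler = quick_sampler(seed = 51, chains = 2L,
                                         warmup = 200L, sampling = 200L))
  diffs <- t(apply(fit$draws$f, 1, diff))
  expect_true(all(diffs >= 0))
  fit_dec <- fit_hpr(dat, constraint = "decreasing",
                     sampler = quick_sampler(seed = 52, chains = 1L,
                                             warmup = 150L, sampling = 100L))
  expect_true(all(t(apply(fit_dec$draws$f, 1, diff)) <= 0))
})

test_that("posterior summaries follow the declared quantile rule", {
  # synthetic fit with four equally weighted draws at one gridpoint
  fit <- structure(list(
    draws = list(f = matrix(c(1, 2, 3, 4), 4, 1)),
    grid = build_grid(0)), class = "hpr_fit")
  s <- summarize_posterior(fit)
  expect_equal(s$point, 2.5)
  expect_equal(s$lower, unname(quantile(1:4, 0.025)))
  expect_equal(s$upper, unname(quantile(1:4, 0.975)))
  s50 <- summarize_posterior(fit, probs = c(0.25, 0.75))
  expect_lt(s50$upper - s50$lower, s$upper - s$lower)
  # degenerate draws: the band collapses onto the point estimate
  fit$draws$f <- matrix(2, 10, 1)
  s0 <- summarize_posterior(fit)
  expect_equal(s0$lower, 2)
  expect_equal(s0$upper, 2)
  expect_equal(s0$point, 2)
  expect_error(summarize_posterior(fit, probs = c(0.9, 0.1)), "increasing")
})

test_that("diagnostics fractions and verdict follow the 5% divergence rule", {
  set.seed(61)
  dat <- hpr_data(rnorm(8), 1:8, family = "gaussian")
  fit <- fit_hpr(dat, sampler = quick_sampler(seed = 61, chains = 2L,
                                              warmup = 150L, sampling = 100L))
  # no (or few) divergences: fraction as observed
  rep0 <- diagnostics_report(fit)
  expect_equal(rep0$divergence_frac, mean(fit$divergent))
  # forced: 500 of 8000 divergences crosses the 5% threshold
  fit2 <- fit
  fit2$divergent <- rep(c(TRUE, FALSE), c(500, 7500))
  fit2$monitor$rhat[] <- 1.0
  rep2 <- diagnostics_report(fit2)
  expect_equal(rep2$divergence_frac, 0.0625)
  expect_equal(rep2$verdict, "warn")
  fit3 <- fit2
  fit3$divergent <- rep(FALSE, 8000)
  expect_equal(diagnostics_report(fit3)$verdict, "ok")
  expect_equal(diagnostics_report(fit3)$divergence_frac, 0)
})

test_that("augmented gridpoints get draws without disturbing observed ones", {
  set.seed(71)
  x <- sort(runif(40, 0, 10))
  y <- true_function("bigstep", x) + rnorm(40, sd = 0.5)
  dat <- hpr_data(y, x, family = "gaussian")
  cfg <- quick_sampler(seed = 71, chains = 2L, warmup = 250L, sampling = 250L)
  fit0 <- fit_hpr(dat, sampler = cfg)
  fit1 <- fit_hpr(dat, x_aug = seq(0.25, 9.75, by = 0.5), sampler = cfg)
  expect_equal(sum(!fit1$grid$is_observed), 20L)
  s0 <- summarize_posterior(fit0)
  s1 <- summarize_posterior(fit1)
  s1_obs <- s1[s1$is_observed, ]
  expect_equal(s1_obs$t, s0$t)
  # posterior means at observed gridpoints statistically unchanged: each
  # difference is small relative to the posterior band
  band <- s0$upper - s0$lower
  expect_lt(max(abs(s1_obs$point - s0$point) / band), 0.5)
  expect_gt(mean(s1$upper - s1$lower) + 1e-9,
            mean(s1_obs$upper - s1_obs$lower))
})
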