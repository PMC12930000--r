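# shared helpers: random raw parameter draws and tiny model instances

random_raw <- function(M, family = "gaussian", p = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- list(alpha_raw = rnorm(1), tau1 = rnorm(1),
              tau2 = 1 / rgamma(1, 0.5, rate = 0.5),
              lambda1 = rnorm(M), lambda2 = 1 / rgamma(M, 0.5, rate = 0.5),
              gamma = rnorm(M))
  if (family == "gaussian") {
    raw$sigma1 <- rnorm(1)
    raw$sigma2 <- 1 / rgamma(1, 0.5, rate = 0.5)
  }
  if (p > 0L) raw$beta_raw <- rnorm(p)
  raw
}

# natural-scale raw list -> unconstrained vector used by the compiled sampler
raw_to_vector <- function(raw) {
  q <- c(raw$alpha_raw, raw$tau1, log(raw$tau2),
         raw$lambda1, log(raw$lambda2), raw$gamma)
  if (!is.null(raw$sigma1)) q <- c(q, raw$sigma1, log(raw$sigma2))
  if (!is.null(raw$beta_raw)) q <- c(q, raw$beta_raw)
  q
}

model_spec_for <- function(data, grid, prior, constraint = "none", Z = NULL) {
  hproc:::model_spec_list(data, grid, prior, constraint,
                          if (is.null(Z)) data$Z else Z)
}

quick_sampler <- function(seed = 1L, chains = 2L, warmup = 200L,
                          sampling = 200L) {
  sampler_config(chains = chains, warmup = warmup, sampling = sampling,
                 seed = seed)
}
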