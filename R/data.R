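#' Construct an observed-data object
#'
#' Bundles the outcome, continuous predictor, optional covariate matrix and
#' outcome family, with family-specific validation: Bernoulli outcomes must
#' lie in \{0, 1\}, Poisson outcomes must be nonnegative integers.
#'
#' @param y numeric outcome vector.
#' @param x numeric predictor vector, same length as `y`.
#' @param Z optional numeric covariate matrix with `length(y)` rows.
#' @param family one of `"gaussian"`, `"bernoulli"`, `"poisson"`; the link is
#'   the canonical pairing (identity, logit, log).
#' @return An object of class `hpr_data`.
#' @export
hpr_data <- function(y, x, Z = NULL, family = c("gaussian", "bernoulli", "poisson")) {
  family <- match.arg(family)
  if (length(y) == 0L) stop("'y' must be nonempty", call. = FALSE)
  if (length(y) != length(x))
    stop("'y' and 'x' must have the same length", call. = FALSE)
  if (!is.numeric(y) || !all(is.finite(y)))
    stop("'y' must be finite numeric", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  check_family_outcome(y, family)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(y))
      stop("'Z' must have one row per observation", call. = FALSE)
    if (!all(is.finite(Z))) stop("'Z' must be finite", call. = FALSE)
  }
  structure(list(y = as.numeric(y), x = as.numeric(x), Z = Z, family = family),
            class = "hpr_data")
}

check_family_outcome <- function(y, family) {
  if (family == "bernoulli" && !all(y %in% c(0, 1))) {
    bad <- which(!(y %in% c(0, 1)))[1L]
    stop(sprintf("bernoulli outcome must be 0/1; offending value %g at row %d",
                 y[bad], bad), call. = FALSE)
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    bad <- which(y < 0 | y != round(y))[1L]
    stop(sprintf("poisson outcome must be nonnegative integers; offending value %g at row %d",
                 y[bad], bad), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hpr_data <- function(x, ...) {
  p <- if (is.null(x$Z)) 0L else ncol(x$Z)
  cat(sprintf("<hpr_data> n = %d, family = %s, covariates = %d\n",
              length(x$y), x$family, p))
  invisible(x)
}

# canonical link / inverse link for each family
family_link <- function(family) {
  switch(family,
         gaussian  = list(g = identity, ginv = identity),
         bernoulli = list(g = stats::qlogis, ginv = stats::plogis),
         poisson   = list(g = log, ginv = exp),
         stop("unknown family: ", family, call. = FALSE))
}

family_code <- function(family) {
  match(family, c("gaussian", "bernoulli", "poisson")) - 1L
}

constraint_code <- function(constraint) {
  switch(constraint, none = 0L, increasing = 1L, decreasing = -1L,
         stop("unknown constraint: ", constraint, call. = FALSE))
}
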