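#' Build the evaluation grid for a horseshoe process fit
#'
#' The latent function is defined on the ordered set of unique predictor
#' values, optionally augmented with extra gridpoints at which no outcome was
#' observed.  Augmented gridpoints receive their own local shrinkage and
#' increment parameters during fitting, so the posterior interpolates (or
#' extrapolates, for points outside the observed range) there.
#'
#' Augmentation points that coincide exactly with an observed value are
#' absorbed into the observed gridpoint; no tolerance-based merging is done,
#' since silently merging nearby points would change the grid size
#' unpredictably.  An augmentation point below `min(x)` becomes the new first
#' gridpoint, so the intercept then refers to the leftmost gridpoint rather
#' than the leftmost observation.
#'
#' @param x numeric vector of observed predictor values (finite, nonempty);
#'   duplicates allowed.
#' @param x_aug optional numeric vector of augmentation points (finite; may be
#'   empty or lie outside the range of `x`).
#' @return An object of class `hpr_grid`: a list with components
#'   \describe{
#'     \item{t}{strictly increasing gridpoint values, length `m`}
#'     \item{obs_index}{for each observation `i`, the position `j` with
#'       `x[i] == t[j]` (1-based)}
#'     \item{is_observed}{logical per gridpoint, `TRUE` iff some observation
#'       falls there}
#'     \item{delta}{spacings `t[k] - t[k-1]`, length `m - 1`}
#'   }
#' @examples
#' g <- build_grid(c(1, 2, 2, 3))
#' g$t                    # 1 2 3
#' g <- build_grid(c(0, 10), x_aug = 5)
#' g$is_observed          # TRUE FALSE TRUE
#' @export
build_grid <- function(x, x_aug = NULL) {
  if (length(x) == 0L) stop("'x' must be nonempty", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (!is.null(x_aug)) {
    if (!is.numeric(x_aug) || !all(is.finite(x_aug)))
      stop("'x_aug' must be finite numeric", call. = FALSE)
  }
  t <- sort(unique(c(x, x_aug)))
  obs_index <- match(x, t)
  is_observed <- t %in% x
  structure(
    list(t = t, obs_index = obs_index, is_observed = is_observed,
         delta = diff(t)),
    class = "hpr_grid")
}

#' @export
print.hpr_grid <- function(x, ...) {
  m <- length(x$t)
  cat(sprintf("<hpr_grid> %d gridpoints (%d observed, %d augmented), range [%g, %g]\n",
              m, sum(x$is_observed), sum(!x$is_observed),
              x$t[1L], x$t[m]))
  invisible(x)
}
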