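#' Ordinary least squares fit for the sampling-bias test
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, coefficient of
#' determination and the two-sided t-test p-value on the slope (`n - 2`
#' degrees of freedom, Gaussian errors).
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, with
#'   `var(x) > 0`.
#' @return An object of class `divergence_ols`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n_points`.
#' @examples
#' fit_ols(c(1, 2, 3), c(1, 2, 2))  # slope 0.5, R^2 = 0.75
#' @export
fit_ols <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 points are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (var(x) == 0) stop("degenerate design: x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n_points = length(x)
  ), class = "divergence_ols")
}

#' @export
print.divergence_ols <- function(x, ...) {
  cat(sprintf(
    "OLS: slope %.4g, intercept %.4g, R^2 = %.3f, P = %.3g (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n_points))
  invisible(x)
}

#' @export
coef.divergence_ols <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Sampling-bias regression
#'
#' Regresses each species' mean intraspecific divergence on its number of
#' sampled individuals. A significant positive slope would indicate that
#' apparent intraspecific variation grows with sampling effort, i.e. that
#' sparsely sampled species understate their true variation; a flat line
#' supports the adequacy of the sampling design. Species with a single
#' specimen are excluded (their mean intraspecific divergence is
#' undefined).
#'
#' @param x a `divergence_summary` (from [divergence_summary()]) or a
#'   `barcode_audit` object.
#' @return A `divergence_ols` fit (see [fit_ols()]) with an added
#'   `points` data frame (`n_specimens`, `mean_intra_pct`).
#' @export
sampling_regression <- function(x) {
  ps <- if (inherits(x, "barcode_audit")) x$divergence$per_species
        else if (inherits(x, "divergence_summary")) x$per_species
        else stop("need a divergence_summary or barcode_audit object")
  if (nrow(ps) < 3L)
    stop("fewer than 3 multi-specimen species: regression undefined")
  fit <- fit_ols(ps$n_specimens, ps$mean_intra_pct)
  fit$points <- ps[, c("species", "n_specimens", "mean_intra_pct")]
  fit
}
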