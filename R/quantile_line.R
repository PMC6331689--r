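#' Fit a population quantile-regression line of a daily trait on age
#'
#' Fits the straight line \eqn{y = a + b \cdot age} minimising the pinball
#' (check) loss \eqn{\sum_i \rho_\tau(y_i - a - b\,x_i)} with
#' \eqn{\rho_\tau(u) = u(\tau - 1[u < 0])}, pooling the daily records of all
#' eligible animals across batches. At \eqn{\tau = 0.05} the line tracks the
#' lower envelope of the cloud of healthy animal-days; days strictly below it
#' are classified as off-feed days.
#'
#' The loss is piecewise linear and convex, and an optimal line passes
#' through two data points (a basic solution of the equivalent linear
#' program). For small inputs the fit enumerates all pair-defined slopes
#' exactly; for large inputs it minimises the convex profile
#' \eqn{f(b) = \min_a \sum \rho_\tau(y - a - bx)} over the slope (the inner
#' minimiser being an order-statistic quantile of \eqn{y - bx}) and then
#' polishes to an exact kink by enumerating pair slopes among the points
#' closest to the provisional line.
#'
#' @param age Numeric vector of ages (days), pooled over animals.
#' @param y Numeric vector of the daily trait (feed intake kg or duration
#'   min), same length as \code{age}. Missing pairs are dropped.
#' @param tau Quantile level in (0, 1). Default 0.05.
#' @param channel Label stored on the object, e.g. \code{"FI"} or
#'   \code{"DUR"}.
#' @param exact_n Inputs up to this size are solved by full pair
#'   enumeration. Default 200.
#' @return Object of class \code{quantile_line} with elements
#'   \code{intercept}, \code{slope}, \code{tau}, \code{loss}, \code{n},
#'   \code{channel}.
#' @examples
#' set.seed(1)
#' x <- rep(70:160, each = 5)
#' y <- 1 + 0.015 * x + rnorm(length(x), 0, 0.3)
#' ql <- fit_quantile_line(x, y, tau = 0.05)
#' mean(y < predict(ql, x))   # close to (and not above) 0.05
#' @export
fit_quantile_line <- function(age, y, tau = 0.05, channel = "FI", exact_n = 200) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0 || tau >= 1) {
    stop_config("tau must lie strictly between 0 and 1")
  }
  keep <- !is.na(age) & !is.na(y)
  x <- as.numeric(age[keep]); yy <- as.numeric(y[keep])
  n <- length(x)
  if (length(unique(x)) < 2) {
    stop_validation("quantile line needs at least 2 distinct ages")
  }

  ## fit on unit-variance data so the solution is exactly equivariant under
  ## rescaling of the response (and better conditioned)
  sc <- stats::sd(yy)
  if (!is.finite(sc) || sc <= 0) sc <- 1
  ys <- yy / sc
  fit <- if (n <= exact_n) qline_exact(x, ys, tau) else qline_profile(x, ys, tau)
  ## rescale the slope, then recompute the intercept as an order statistic
  ## of the original-unit residuals: one data point then sits exactly on
  ## the line, which keeps the coverage bracket exact in original units
  b <- fit$b * sc
  r <- yy - b * x
  a <- qline_intercept(r, tau)
  fit <- list(a = a, b = b, loss = pinball_loss(r - a, tau))
  structure(list(intercept = fit$a, slope = fit$b, tau = tau,
                 loss = fit$loss, n = n, channel = channel),
            class = "quantile_line")
}

pinball_loss <- function(r, tau) {
  sum(r * (tau - (r < 0)))
}

## Optimal intercept for a fixed slope: a tau-quantile (order statistic) of
## the detrended values. Using the ceiling(n*tau)-th order statistic keeps
## #\{strictly below\} <= tau*n <= #\{below or on\} by construction.
qline_intercept <- function(r, tau) {
  k <- max(1L, ceiling(length(r) * tau))
  sort.int(r, partial = k)[k]
}

## Exact fit by enumerating candidate slopes from all point pairs. The
## optimum of a piecewise-linear convex profile sits at a kink, and every
## kink slope is defined by a pair of points.
qline_exact <- function(x, y, tau) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[1, ]] - x[ij[2, ]]
  ok <- dx != 0
  slopes <- unique(c(0, (y[ij[1, ]] - y[ij[2, ]])[ok] / dx[ok]))
  best <- NULL
  for (b in slopes) {
    r <- y - b * x
    a <- qline_intercept(r, tau)
    loss <- pinball_loss(r - a, tau)
    if (is.null(best) || loss < best$loss) best <- list(a = a, b = b, loss = loss)
  }
  best
}

## Large-n fit: 1-D convex minimisation of the slope profile, then an exact
## polish using pair slopes among the points nearest the provisional line.
qline_profile <- function(x, y, tau, n_active = 40L) {
  prof <- function(b) {
    r <- y - b * x
    pinball_loss(r - qline_intercept(r, tau), tau)
  }
  ## Bracket the slope by robust data-driven bounds.
  b0 <- (stats::quantile(y, 0.9) - stats::quantile(y, 0.1)) /
        max(diff(range(x)), .Machine$double.eps)
  lo <- -3 * abs(b0) - 1; hi <- 3 * abs(b0) + 1
  opt <- stats::optimize(prof, c(lo, hi), tol = 1e-10)
  b <- opt$minimum
  ## Polish: the exact optimum is a kink defined by two near-active points.
  r <- y - b * x
  a <- qline_intercept(r, tau)
  act <- order(abs(r - a))[seq_len(min(n_active, length(x)))]
  ## Evaluate all pair slopes among the active set on the FULL data.
  ij <- utils::combn(length(act), 2)
  dx <- x[act[ij[1, ]]] - x[act[ij[2, ]]]
  ok <- dx != 0
  slopes <- unique(c(b, (y[act[ij[1, ]]] - y[act[ij[2, ]]])[ok] / dx[ok]))
  best <- NULL
  for (bb in slopes) {
    rr <- y - bb * x
    aa <- qline_intercept(rr, tau)
    loss <- pinball_loss(rr - aa, tau)
    if (is.null(best) || loss < best$loss) best <- list(a = aa, b = bb, loss = loss)
  }
  best
}

#' @export
print.quantile_line <- function(x, ...) {
  cat(sprintf("%g%% quantile regression line (%s): y = %.6g %+.6g * age  [n = %d days]\n",
              100 * x$tau, x$channel, x$intercept, x$slope, x$n))
  invisible(x)
}

#' Predict the quantile line at given ages
#'
#' @param object A \code{quantile_line}.
#' @param age Ages (days) at which to evaluate the line.
#' @param ... Unused.
#' @return Numeric vector of line values.
#' @export
predict.quantile_line <- function(object, age, ...) {
  object$intercept + object$slope * as.numeric(age)
}
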