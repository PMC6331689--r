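#' Smooth an animal's sparse body weights into a daily growth curve
#'
#' Pigs are weighed roughly every three weeks, yet growth and efficiency
#' traits need a weight for every day. A locally weighted polynomial
#' regression (LOESS: tricube kernel, span 0.75, local degree 2, no
#' robustness iterations, exact "direct" surface) of weight on age is
#' evaluated at every integer age between the first and last observed
#' weighing. Animals with fewer than \code{min_loess} weights — typically
#' early deaths — fall back to piecewise-linear interpolation, flagged in
#' the output; with fewer than 2 weights no curve is fit.
#'
#' Extrapolation outside the observed age range is never performed; callers
#' clip phases to the curve range.
#'
#' @param age Observation ages (days), strictly increasing.
#' @param weight Observed body weights (kg), positive.
#' @param span LOESS span (fraction of points in each local neighbourhood).
#'   Default 0.75.
#' @param degree Local polynomial degree, 1 or 2. Default 2.
#' @param min_loess Minimum observations for a LOESS fit. Default 4.
#' @return Object of class \code{growth_curve}: list with \code{age}
#'   (integer grid), \code{pred_weight}, \code{method} ("loess" or
#'   "linear"), \code{fit_quality} (correlation of predictions with
#'   observations at observed ages), plus the inputs. \code{NULL} when a
#'   curve cannot be fit.
#' @examples
#' a <- seq(30, 170, by = 21)
#' w <- 8 + 0.75 * (a - 30) + rnorm(length(a), 0, 0.5)
#' gc <- fit_loess_weights(a, w)
#' gc$fit_quality
#' @export
fit_loess_weights <- function(age, weight, span = 0.75, degree = 2,
                              min_loess = 4) {
  keep <- !is.na(age) & !is.na(weight)
  age <- as.numeric(age[keep]); weight <- as.numeric(weight[keep])
  o <- order(age); age <- age[o]; weight <- weight[o]
  if (any(weight <= 0)) stop_validation("body weights must be positive")
  if (any(duplicated(age))) stop_validation("duplicate weighing ages for one animal")
  n <- length(age)
  if (n < 2) return(NULL)
  grid <- seq(ceiling(age[1]), floor(age[n]))
  if (n < min_loess) {
    pred <- stats::approx(age, weight, xout = grid)$y
    at_obs <- stats::approx(age, weight, xout = age)$y
    method <- "linear"
  } else {
    ## small-n local fits can touch the pseudoinverse path; those fits are
    ## still well-defined and fit_quality reports how well they track
    fit <- suppressWarnings(
      stats::loess(weight ~ age, span = span, degree = degree,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")))
    pred <- as.numeric(suppressWarnings(stats::predict(fit, data.frame(age = grid))))
    at_obs <- as.numeric(suppressWarnings(stats::predict(fit, data.frame(age = age))))
    method <- "loess"
  }
  fq <- suppressWarnings(stats::cor(at_obs, weight))
  if (is.na(fq)) fq <- 1  # zero-variance observations fit exactly
  structure(list(age = grid, pred_weight = pred, method = method,
                 fit_quality = fq, obs_age = age, obs_weight = weight),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth curve (%s): ages %d-%d, %d observed weights, fit quality %.4f\n",
              x$method, min(x$age), max(x$age), length(x$obs_age), x$fit_quality))
  invisible(x)
}

#' Average daily gain over a phase as a regression slope
#'
#' Ordinary-least-squares slope of the predicted daily weights on age over
#' \code{[start_age, end_age]}. The phase is clipped to the curve's range;
#' a clipped or out-of-range phase shorter than 2 days yields \code{NA}.
#' Nursery ADG runs from quarantine entry to the first feed-intake day,
#' finishing ADG from the first to the last feed-intake day.
#'
#' @param curve A \code{\link{fit_loess_weights}} object.
#' @param start_age,end_age Phase bounds in days.
#' @return Slope in kg/day, or \code{NA}.
#' @export
phase_adg <- function(curve, start_age, end_age) {
  if (is.null(curve)) return(NA_real_)
  if (is.na(start_age) || is.na(end_age)) return(NA_real_)
  lo <- max(start_age, min(curve$age))
  hi <- min(end_age, max(curve$age))
  sel <- curve$age >= lo & curve$age <= hi
  if (sum(sel) < 2) return(NA_real_)
  x <- curve$age[sel]; y <- curve$pred_weight[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Fit growth curves for all animals
#'
#' @param weights Data frame with columns \code{animal_id}, \code{age},
#'   \code{weight}.
#' @param ... Passed to [fit_loess_weights()].
#' @return List with \code{daily} (data frame: \code{animal_id}, \code{age},
#'   \code{pred_weight}, \code{method}) and \code{curves} (named list of
#'   \code{growth_curve} objects; animals with < 2 weights absent).
#' @export
fit_growth_curves <- function(weights, ...) {
  assert_cols(weights, c("animal_id", "age", "weight"), "weights")
  curves <- lapply(split(weights, weights$animal_id),
                   function(w) fit_loess_weights(w$age, w$weight, ...))
  curves <- Filter(Negate(is.null), curves)
  daily <- do.call(rbind, lapply(names(curves), function(id) {
    cv <- curves[[id]]
    data.frame(animal_id = id, age = cv$age, pred_weight = cv$pred_weight,
               method = cv$method)
  }))
  rownames(daily) <- NULL
  list(daily = daily, curves = curves)
}

#' Nursery and finishing ADG for all animals
#'
#' @param curves Named list of growth curves from [fit_growth_curves()].
#' @param animals Animal table with \code{animal_id},
#'   \code{quarantine_entry_age}.
#' @param daily Cleaned daily feed records; each animal's first and last
#'   feed-intake day delimit the phases.
#' @return Data frame: \code{animal_id}, \code{nur_adg}, \code{fin_adg}.
#' @export
phase_adg_table <- function(curves, animals, daily) {
  daily <- canonical_daily(daily)
  fi_span <- do.call(rbind, lapply(split(daily, daily$animal_id), function(d) {
    obs <- d$age[!is.na(d$fi)]
    data.frame(animal_id = d$animal_id[1],
               first_fi = if (length(obs)) min(obs) else NA_real_,
               last_fi  = if (length(obs)) max(obs) else NA_real_)
  }))
  rows <- lapply(animals$animal_id, function(id) {
    cv <- curves[[id]]
    sp <- fi_span[fi_span$animal_id == id, ]
    qa <- animals$quarantine_entry_age[animals$animal_id == id]
    first_fi <- if (nrow(sp)) sp$first_fi else NA_real_
    last_fi <- if (nrow(sp)) sp$last_fi else NA_real_
    data.frame(animal_id = id,
               nur_adg = phase_adg(cv, qa, first_fi),
               fin_adg = phase_adg(cv, first_fi, last_fi))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
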