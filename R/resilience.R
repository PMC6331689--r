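#' Within-animal RMSE of daily feed intake or duration about its age trend
#'
#' Fits an ordinary-least-squares line of the daily value on age within one
#' animal and returns the root mean square of the residuals,
#' \eqn{\sqrt{SSE/n}}. A resilient animal tracks its own trend closely (small
#' RMSE); illness episodes produce large deviations and inflate it.
#'
#' @param age Ages (days) of one animal's daily records.
#' @param value Daily feed intake (kg) or feeder duration (min); \code{NA}s
#'   dropped pairwise with \code{age}.
#' @param denominator \code{"n"} (default, literal root-mean-square) or
#'   \code{"n-2"} (residual degrees of freedom).
#' @return RMSE in the units of \code{value}, or \code{NA} with fewer than
#'   3 usable days.
#' @examples
#' rmse_trait(1:3, c(1, 3, 2))   # sqrt((1 + 0.25 + 1)/3) = 0.866...
#' @export
rmse_trait <- function(age, value, denominator = c("n", "n-2")) {
  denominator <- match.arg(denominator)
  keep <- !is.na(age) & !is.na(value)
  x <- as.numeric(age[keep]); y <- as.numeric(value[keep])
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, x), y)
  sse <- sum(fit$residuals^2)
  sqrt(sse / if (denominator == "n") n else n - 2)
}

#' Proportion of off-feed days for one animal
#'
#' A day is off-feed when its value lies strictly below the population
#' quantile-regression line at that age (a negative residual); ties sit on
#' the line and count as on-feed. The proportion is over the animal's
#' non-missing days.
#'
#' @param age,value One animal's daily ages and values (same channel the
#'   line was fitted on).
#' @param line A \code{\link{fit_quantile_line}} object.
#' @return Proportion in \eqn{[0, 1]}, or \code{NA} if no usable days.
#' @export
qr_trait <- function(age, value, line) {
  stopifnot(inherits(line, "quantile_line"))
  keep <- !is.na(age) & !is.na(value)
  if (!any(keep)) return(NA_real_)
  pred <- predict(line, age[keep])
  ## a day within rounding error of the line sits on it, not below it
  below <- value[keep] < pred - 1e-8 * (1 + abs(pred))
  mean(below)
}

#' Mortality, treatment count, and treatment rate per 180 days
#'
#' Validation traits for the resilience phenotypes. \code{mortality} is 1 if
#' the animal died before slaughter, else 0. \code{trt} counts individual
#' medical treatments (drug injections to that animal; batch-level group
#' treatments excluded) and is recorded only for animals surviving to
#' slaughter. \code{trt180} standardises the count to a 180-day basis,
#' \eqn{(\mathrm{count} / \mathrm{last\ alive\ age}) \times 180}, and is
#' recorded for animals that reached 65 days of age (the approximate age of
#' entry into finishing); for survivors the denominator is age at slaughter.
#' An animal with three treatments dying at day 80 gets
#' \eqn{(3/80)\times 180 = 6.75}.
#'
#' @param death_age Age at death in days, or \code{NA} if the animal
#'   survived to slaughter.
#' @param slaughter_age Age at slaughter in days (ignored for dead animals).
#' @param treatment_ages Ages of the animal's individual treatments (vector;
#'   may be empty).
#' @return List with \code{mortality} (0/1), \code{trt} (count or \code{NA})
#'   and \code{trt180} (rate or \code{NA}).
#' @examples
#' treatment_traits(death_age = 80, slaughter_age = NA,
#'                  treatment_ages = c(40, 55, 70))$trt180   # 6.75
#' @export
treatment_traits <- function(death_age, slaughter_age, treatment_ages = numeric(0)) {
  died <- !is.na(death_age)
  last_age <- if (died) death_age else slaughter_age
  if (is.na(last_age) || last_age <= 0) {
    stop_validation("an animal needs a positive death or slaughter age")
  }
  if (length(treatment_ages) && any(treatment_ages > last_age)) {
    stop_validation("treatment recorded after the animal's last alive age")
  }
  n_trt <- length(treatment_ages)
  list(mortality = as.integer(died),
       trt = if (died) NA_integer_ else n_trt,
       trt180 = if (last_age >= 65) n_trt / last_age * 180 else NA_real_)
}

#' Build the per-animal resilience phenotype table
#'
#' Applies the 60-day eligibility filter, fits the pooled 5% quantile lines
#' for feed intake and duration on the eligible animals' days, and computes
#' RMSE_FI, RMSE_DUR, QR_FI, QR_DUR together with mortality, TRT and TRT180
#' for every animal.
#'
#' @param daily Cleaned daily records ([clean_daily()]).
#' @param animals Animal table with columns \code{animal_id}, \code{batch},
#'   \code{pen}, \code{death_age} (\code{NA} = survived),
#'   \code{slaughter_age}.
#' @param treatments Data frame of individual treatments with columns
#'   \code{animal_id}, \code{age}; may have zero rows.
#' @param tau Quantile level for the off-feed lines. Default 0.05.
#' @param min_days Minimum feed-intake days for the resilience phenotypes.
#'   Default 60.
#' @param rmse_denominator Passed to [rmse_trait()].
#' @return List with \code{phenotypes} (one row per animal: resilience and
#'   validation traits plus \code{n_days}) and \code{lines} (the two fitted
#'   \code{quantile_line} objects, named \code{FI} and \code{DUR}).
#' @export
resilience_table <- function(daily, animals, treatments = NULL,
                             tau = 0.05, min_days = 60,
                             rmse_denominator = "n") {
  daily <- canonical_daily(daily)
  assert_cols(animals, c("animal_id", "death_age", "slaughter_age"), "animals")
  if (is.null(treatments)) {
    treatments <- data.frame(animal_id = character(0), age = numeric(0))
  }
  elig <- eligible_for_resilience(daily, min_days = min_days)
  elig_ids <- names(elig)[elig]
  pool <- daily[daily$animal_id %in% elig_ids, , drop = FALSE]
  lines <- list(
    FI  = fit_quantile_line(pool$age, pool$fi,  tau = tau, channel = "FI"),
    DUR = fit_quantile_line(pool$age, pool$dur, tau = tau, channel = "DUR"))

  by_animal <- split(daily, daily$animal_id)
  rows <- lapply(animals$animal_id, function(id) {
    d <- by_animal[[id]]
    a <- animals[animals$animal_id == id, ]
    tr <- treatment_traits(a$death_age, a$slaughter_age,
                           treatments$age[treatments$animal_id == id])
    ok <- !is.null(d) && isTRUE(elig[id])
    data.frame(
      animal_id = id,
      n_days = if (is.null(d)) 0L else sum(!is.na(d$fi)),
      rmse_fi  = if (ok) rmse_trait(d$age, d$fi,  denominator = rmse_denominator) else NA_real_,
      rmse_dur = if (ok) rmse_trait(d$age, d$dur, denominator = rmse_denominator) else NA_real_,
      qr_fi  = if (ok) qr_trait(d$age, d$fi,  lines$FI)  else NA_real_,
      qr_dur = if (ok) qr_trait(d$age, d$dur, lines$DUR) else NA_real_,
      mortality = tr$mortality, trt = tr$trt, trt180 = tr$trt180)
  })
  phen <- do.call(rbind, rows)
  rownames(phen) <- NULL
  list(phenotypes = phen, lines = lines)
}
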