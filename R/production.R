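#' Average daily feed intake over finishing
#'
#' Arithmetic mean of the non-missing daily feed-intake records during the
#' finishing period.
#'
#' @param fi Daily feed-intake values (kg) for one animal's finishing days.
#' @return Mean kg/day, or \code{NA} with no usable days.
#' @export
adfi <- function(fi) {
  fi <- fi[!is.na(fi)]
  if (!length(fi)) return(NA_real_)
  mean(fi)
}

#' Feed conversion ratio over a phase
#'
#' Total feed consumed over the phase divided by the body-weight gain over
#' the same phase, with gain taken from the smoothed daily growth curve at
#' the phase endpoints.
#'
#' @param fi Daily feed-intake records (kg) over the phase; \code{NA}s
#'   ignored.
#' @param weight_start,weight_end Predicted body weight (kg) at the phase
#'   start and end.
#' @return kg feed per kg gain, or \code{NA} when the gain is not positive
#'   (with a warning) or an endpoint weight is missing.
#' @export
fcr <- function(fi, weight_start, weight_end) {
  if (is.na(weight_start) || is.na(weight_end)) return(NA_real_)
  gain <- weight_end - weight_start
  if (gain <= 0) {
    warning("non-positive body-weight gain; FCR undefined")
    return(NA_real_)
  }
  sum(fi, na.rm = TRUE) / gain
}

#' Residual feed intake
#'
#' Residual of average daily feed intake from a linear model with fixed
#' effects (batch, finishing start age, pen) and the energy-sink covariates
#' average finisher body weight (optionally metabolic, weight^0.75),
#' finishing average daily gain, and ultrasound backfat. Animals eating more
#' than their growth, maintenance and fat deposition predict have positive
#' RFI (poor net feed efficiency).
#'
#' @param data Data frame with columns \code{adfi}, \code{avg_weight},
#'   \code{fin_adg}, \code{ultrasound_bf} and the fixed-effect columns.
#' @param fixed Character vector of fixed-effect column names treated as
#'   factors or covariates as their class dictates. Default
#'   \code{c("batch", "fin_start_age", "pen")}.
#' @param metabolic Use metabolic body weight (\code{avg_weight^0.75}) as
#'   the weight covariate. Default \code{TRUE}.
#' @return Numeric vector of residuals (kg/day), \code{NA} for rows with
#'   incomplete covariates; mean over complete rows is 0 by construction.
#'   Aliased design columns are dropped with a message.
#' @export
rfi <- function(data, fixed = c("batch", "fin_start_age", "pen"),
                metabolic = TRUE) {
  assert_cols(data, c("adfi", "avg_weight", "fin_adg", "ultrasound_bf"), "RFI input")
  fixed <- intersect(fixed, names(data))
  d <- data
  d$..wt <- if (metabolic) d$avg_weight^0.75 else d$avg_weight
  for (f in fixed) if (!is.numeric(d[[f]])) d[[f]] <- factor(d[[f]])
  ## single-level factors and constant covariates carry no contrast
  fixed <- Filter(function(f) {
    v <- d[[f]][!is.na(d[[f]])]
    length(unique(v)) > 1
  }, fixed)
  rhs <- c(fixed, "..wt", "fin_adg", "ultrasound_bf")
  form <- stats::as.formula(paste("adfi ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = d, na.action = stats::na.exclude)
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped)) {
    message("RFI design rank-deficient; dropped: ", paste(dropped, collapse = ", "))
  }
  as.numeric(stats::residuals(fit))
}

#' Dressing proportion
#'
#' Warm carcass weight (head on, leaf lard in) divided by live weight just
#' before slaughter.
#'
#' @param cwt Carcass weight, kg.
#' @param live_weight Live weight prior to slaughter, kg.
#' @return Proportion; values above 0.95 are flagged with a warning as
#'   implausible.
#' @export
dressing <- function(cwt, live_weight) {
  if (any(!is.na(live_weight) & live_weight <= 0)) {
    stop_validation("live weight must be positive")
  }
  drs <- cwt / live_weight
  if (any(!is.na(drs) & drs > 0.95)) {
    warning("dressing proportion > 0.95 — implausible carcass/live weight pair")
  }
  drs
}

#' Carcass lean yield from backfat and loin depth
#'
#' Evaluates the Quebec lean-yield prediction polynomial
#' \deqn{LYLD = 68.1863 - 0.7833\,CBF + 0.0689\,CLD + 0.008\,CBF^2
#'       - 0.0002\,CLD^2 + 0.0006\,CBF\,CLD}
#' with backfat and loin depth in millimetres. The prediction is dominated
#' by backfat; over observed carcass ranges it decreases monotonically in
#' CBF.
#'
#' @param cbf Carcass backfat, mm (non-negative).
#' @param cld Carcass loin depth, mm (non-negative).
#' @return Lean yield, percent.
#' @examples
#' lean_yield(0, 0)          # the polynomial's intercept, 68.1863
#' lean_yield(17.96, 60.69)  # near the cohort mean lean yield
#' @export
lean_yield <- function(cbf, cld) {
  if (any(!is.na(cbf) & cbf < 0) || any(!is.na(cld) & cld < 0)) {
    stop_validation("backfat and loin depth must be non-negative")
  }
  68.1863 - 0.7833 * cbf + 0.0689 * cld +
    0.008 * cbf^2 - 0.0002 * cld^2 + 0.0006 * cbf * cld
}

#' Build the per-animal production trait table
#'
#' Computes ADFI, FCR, average finisher weight, carcass traits and residual
#' feed intake for animals that completed the relevant phase.
#'
#' @param daily Cleaned daily feed records.
#' @param growth Daily growth-curve table from [fit_growth_curves()]
#'   (columns \code{animal_id}, \code{age}, \code{pred_weight}).
#' @param animals Animal table (\code{animal_id}, \code{batch}, \code{pen},
#'   \code{finishing_start_age}, \code{death_age}, \code{slaughter_age}).
#' @param adg ADG table from [phase_adg_table()] (columns \code{animal_id},
#'   \code{nur_adg}, \code{fin_adg}).
#' @param carcass Optional carcass table (\code{animal_id}, \code{cwt},
#'   \code{cbf}, \code{cld}, \code{live_weight}, \code{ultrasound_bf}).
#' @param metabolic Passed to [rfi()].
#' @return Data frame, one row per animal, with columns \code{adfi},
#'   \code{fcr}, \code{avg_weight}, \code{rfi}, \code{cwt}, \code{drs},
#'   \code{lyld}, \code{cbf}, \code{cld} (traits \code{NA} where the phase
#'   or carcass data is incomplete).
#' @export
production_table <- function(daily, growth, animals, adg, carcass = NULL,
                             metabolic = TRUE) {
  daily <- canonical_daily(daily)
  by_daily <- split(daily, daily$animal_id)
  by_growth <- split(growth, growth$animal_id)
  rows <- lapply(animals$animal_id, function(id) {
    a <- animals[animals$animal_id == id, ]
    d <- by_daily[[id]]
    g <- by_growth[[id]]
    finished <- is.na(a$death_age)
    out <- data.frame(animal_id = id, adfi = NA_real_, fcr = NA_real_,
                      avg_weight = NA_real_)
    if (finished && !is.null(d) && nrow(d)) {
      out$adfi <- adfi(d$fi)
      if (!is.null(g) && nrow(g) >= 2) {
        span <- range(d$age)
        gg <- g[g$age >= span[1] & g$age <= span[2], ]
        if (nrow(gg) >= 2) {
          out$fcr <- suppressWarnings(
            fcr(d$fi, gg$pred_weight[1], gg$pred_weight[nrow(gg)]))
          out$avg_weight <- mean(gg$pred_weight)
        }
      }
    }
    out
  })
  prod <- do.call(rbind, rows)

  if (!is.null(carcass) && nrow(carcass)) {
    assert_cols(carcass, c("animal_id", "cwt", "cbf", "cld", "live_weight"),
                "carcass")
    m <- match(prod$animal_id, carcass$animal_id)
    prod$cwt <- carcass$cwt[m]
    prod$cbf <- carcass$cbf[m]
    prod$cld <- carcass$cld[m]
    prod$drs <- ifelse(is.na(m), NA_real_,
                       suppressWarnings(dressing(carcass$cwt[m], carcass$live_weight[m])))
    prod$lyld <- lean_yield(prod$cbf, prod$cld)
    prod$ultrasound_bf <- if ("ultrasound_bf" %in% names(carcass))
      carcass$ultrasound_bf[m] else prod$cbf
  } else {
    prod$cwt <- prod$cbf <- prod$cld <- prod$drs <- prod$lyld <-
      prod$ultrasound_bf <- NA_real_
  }

  m <- match(prod$animal_id, animals$animal_id)
  prod$batch <- animals$batch[m]
  prod$pen <- if ("pen" %in% names(animals)) animals$pen[m] else NA
  prod$fin_start_age <- if ("finishing_start_age" %in% names(animals))
    animals$finishing_start_age[m] else NA_real_
  ma <- match(prod$animal_id, adg$animal_id)
  prod$nur_adg <- adg$nur_adg[ma]
  prod$fin_adg <- adg$fin_adg[ma]

  prod$rfi <- tryCatch(rfi(prod, metabolic = metabolic),
                       error = function(e) rep(NA_real_, nrow(prod)))
  rownames(prod) <- NULL
  prod
}
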