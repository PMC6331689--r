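#' Set implausible daily feed-intake totals to missing
#'
#' Daily feed-intake totals strictly greater than \code{cap} kilograms are set
#' to missing. Such totals arise from feeder malfunctions or mis-assigned
#' visits; a grow-finish pig does not eat more than about 5 kg in a day.
#' Feeder duration is never capped.
#'
#' @param daily Data frame of daily records with columns \code{animal_id},
#'   \code{age} (days), \code{fi} (kg, may be \code{NA}) and \code{dur}
#'   (minutes, may be \code{NA}).
#' @param cap Upper plausibility bound in kg/day; values strictly above it are
#'   set missing. Default 5.
#' @return List with \code{records} (the daily table, canonically sorted, with
#'   \code{imputed_fi}/\code{imputed_dur} flag columns added if absent) and
#'   \code{report}, a \code{\link{cleaning_report}}.
#' @seealso [impute_rolling()], [eligible_for_resilience()]
#' @examples
#' d <- data.frame(animal_id = "p1", age = 1:3, fi = c(2.1, 5.0, 6.3),
#'                 dur = c(60, 70, 80))
#' cap_daily_fi(d)$records$fi   # 6.3 -> NA; exactly 5.0 is kept
#' @export
cap_daily_fi <- function(daily, cap = 5) {
  if (!is.numeric(cap) || length(cap) != 1 || is.na(cap) || cap < 0) {
    stop_config("cap must be a single non-negative number, got ", format(cap))
  }
  daily <- canonical_daily(daily)
  assert_cols(daily, c("fi", "dur"), "daily records")
  if (is.null(daily$imputed_fi)) daily$imputed_fi <- FALSE
  if (is.null(daily$imputed_dur)) daily$imputed_dur <- FALSE
  over <- !is.na(daily$fi) & daily$fi > cap
  daily$fi[over] <- NA_real_
  list(records = daily,
       report = cleaning_report(n_capped = sum(over)))
}

#' Fill missing daily values by a centred rolling average within animal
#'
#' Each missing feed-intake (and, separately, duration) value is replaced by
#' the mean of the *originally observed* values on the calendar days within
#' \code{(window - 1) / 2} days of the gap, within the same animal. A centred
#' 5-day window fills a single missing day from up to four neighbours and
#' still fills both days of a two-day gap from the flanking observed days.
#' Because only originally observed values are used, the result does not
#' depend on fill order and the operation is idempotent. Days with no
#' observed neighbour in the window stay missing.
#'
#' @param daily Daily records as produced by [cap_daily_fi()].
#' @param window Odd window width in days, at least 3. Default 5.
#' @param sides \code{"centred"} (default) or \code{"trailing"} (use only the
#'   preceding \code{window - 1} days).
#' @return List with \code{records} (gaps filled, \code{imputed_*} flags set)
#'   and \code{report}, a \code{\link{cleaning_report}} with counts of filled
#'   and still-missing values (feed intake and duration combined).
#' @examples
#' d <- data.frame(animal_id = "p1", age = 1:5, fi = c(1, 2, NA, 4, 5),
#'                 dur = c(30, 40, NA, 60, 70))
#' impute_rolling(d)$records$fi[3]   # mean(1, 2, 4, 5) = 3
#' @export
impute_rolling <- function(daily, window = 5, sides = c("centred", "trailing")) {
  sides <- match.arg(sides)
  if (!is.numeric(window) || length(window) != 1 || is.na(window) ||
      window < 3 || window %% 2 == 0) {
    stop_config("window must be an odd integer >= 3, got ", format(window))
  }
  daily <- canonical_daily(daily)
  assert_cols(daily, c("fi", "dur"), "daily records")
  if (is.null(daily$imputed_fi)) daily$imputed_fi <- FALSE
  if (is.null(daily$imputed_dur)) daily$imputed_dur <- FALSE
  half <- (window - 1) / 2
  lags <- if (sides == "centred") setdiff(-half:half, 0L) else -(window - 1):-1

  n_imputed <- 0L
  n_unfilled <- 0L
  for (channel in c("fi", "dur")) {
    flag <- paste0("imputed_", channel)
    vals <- split(seq_len(nrow(daily)), daily$animal_id)
    for (idx in vals) {
      v <- daily[[channel]][idx]
      miss <- which(is.na(v))
      if (!length(miss)) next
      age <- daily$age[idx]
      obs_age <- age[!is.na(v)]
      obs_val <- v[!is.na(v)]
      for (m in miss) {
        nb <- obs_val[obs_age %in% (age[m] + lags)]
        if (length(nb)) {
          daily[[channel]][idx[m]] <- mean(nb)
          daily[[flag]][idx[m]] <- TRUE
          n_imputed <- n_imputed + 1L
        } else {
          n_unfilled <- n_unfilled + 1L
        }
      }
    }
  }
  list(records = daily,
       report = cleaning_report(n_imputed = n_imputed, n_unfilled = n_unfilled))
}

#' Eligibility of an animal for the resilience phenotypes
#'
#' An animal receives RMSE and off-feed-proportion phenotypes only with at
#' least \code{min_days} animal-days of non-missing feed intake. Without the
#' floor, animals dying early in finishing would cluster at the low end of
#' the RMSE distribution and look spuriously resilient. Imputed days count by
#' default (\code{count_imputed = FALSE} restricts to originally observed
#' days).
#'
#' @param daily Cleaned daily records (all animals).
#' @param min_days Minimum number of non-missing feed-intake days. Default 60.
#' @param count_imputed Should imputed days count toward the minimum? Default
#'   \code{TRUE}.
#' @return Named logical vector, one element per animal.
#' @export
eligible_for_resilience <- function(daily, min_days = 60, count_imputed = TRUE) {
  daily <- canonical_daily(daily)
  assert_cols(daily, "fi", "daily records")
  ok <- !is.na(daily$fi)
  if (!count_imputed && !is.null(daily$imputed_fi)) ok <- ok & !daily$imputed_fi
  counts <- tapply(ok, daily$animal_id, sum)
  out <- counts >= min_days
  out[is.na(out)] <- FALSE
  out
}

#' Cleaning report constructor
#'
#' Tallies of record-cleaning actions: values set missing by the intake cap,
#' values filled by the rolling average, and values left missing.
#'
#' @param n_capped,n_imputed,n_unfilled Non-negative counts.
#' @return Object of class \code{cleaning_report}.
#' @export
cleaning_report <- function(n_capped = 0L, n_imputed = 0L, n_unfilled = 0L) {
  stopifnot(n_capped >= 0, n_imputed >= 0, n_unfilled >= 0)
  structure(list(n_capped = as.integer(n_capped),
                 n_imputed = as.integer(n_imputed),
                 n_unfilled = as.integer(n_unfilled)),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Daily-record cleaning report\n",
      "  capped (> cap, set missing): ", x$n_capped, "\n",
      "  imputed by rolling average : ", x$n_imputed, "\n",
      "  left missing               : ", x$n_unfilled, "\n", sep = "")
  invisible(x)
}

#' Clean daily feed records end to end
#'
#' Convenience wrapper: cap implausible intakes, then fill gaps by the
#' centred rolling average.
#'
#' @inheritParams cap_daily_fi
#' @inheritParams impute_rolling
#' @return List with \code{records} and a merged \code{report}.
#' @export
clean_daily <- function(daily, cap = 5, window = 5, sides = "centred") {
  capped <- cap_daily_fi(daily, cap = cap)
  filled <- impute_rolling(capped$records, window = window, sides = sides)
  list(records = filled$records,
       report = cleaning_report(n_capped = capped$report$n_capped,
                                n_imputed = filled$report$n_imputed,
                                n_unfilled = filled$report$n_unfilled))
}
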