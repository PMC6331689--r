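#' Configuration for the disease-challenge cohort simulator
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' describe a wean-to-finish natural-challenge cohort of the scale the
#' analysis is designed for: 21 batches of 64 pigs entering continuously, a
#' half-sib sire/dam pedigree, daily feed intake rising through finishing to
#' a mean near 2.2 kg/day, feeder duration coupled to intake through an
#' animal-specific intake rate, illness episodes whose frequency and depth
#' grow with a heritable latent susceptibility, treatments triggered by
#' episode severity, and severe episodes causing death — with the default
#' mortality threshold set so the cohort realises roughly 26% mortality.
#'
#' @param n_batches Number of entry batches. Default 21.
#' @param pigs_per_batch Pigs per batch. Default 64.
#' @param n_sires,dams_per_sire Half-sib family structure; pigs draw a sire
#'   uniformly and a dam uniformly within sire. Defaults 60 and 4.
#' @param trait_h2 Named heritabilities in \[0, 1\] for the latent traits
#'   \code{susceptibility}, \code{appetite}, \code{growth}.
#' @param genetic_corr 3x3 genetic correlation matrix over the latent traits
#'   (order susceptibility, appetite, growth); must be positive
#'   semi-definite with unit diagonal.
#' @param baseline_fi_intercept Mean feed intake (kg/day) at finishing
#'   start. Default 1.4.
#' @param baseline_fi_slope Increase in feed intake per day of age
#'   (kg/day/day). Default 0.015.
#' @param baseline_dur_mean Mean feeder duration (min/day) mid-finishing;
#'   fixes the mean animal intake rate. Default 65.
#' @param fi_noise_sd,dur_noise_sd Day-to-day residual noise (kg, min).
#'   Defaults 0.38 and 6.
#' @param episode_rate Illness episodes per animal per 100 days at average
#'   susceptibility. Default 1.2.
#' @param episode_depth_range Fractional feed-intake reduction at episode
#'   plateau, within \[0, 1\]. Default c(0.3, 1).
#' @param episode_length_range Plateau length in days (2-day onset and
#'   recovery ramps are added around it). Default c(3, 12).
#' @param treatment_severity_threshold Episode severity (plateau depth x
#'   length, in lost feed-days) above which an individual treatment is
#'   given. Default 2.5.
#' @param mortality_severity_threshold Severity above which the episode is
#'   fatal. Default 7.08 (calibrated once by bisection so the default
#'   cohort realises ~26\% mortality).
#' @param finishing_age_span Ages (days) delimiting finishing, when the
#'   electronic feeders record intake. Default c(70, 181).
#' @param quarantine_entry_age Age at entry into the quarantine nursery.
#'   Default 21.
#' @param spike_rate Probability a recorded day shows a spurious feeder
#'   spike (6-8 kg), exercising the intake cap. Default 0.002.
#' @param missing_rate Probability a finishing day's record is lost.
#'   Default 0.01.
#' @param seasonality Amplitude of a sinusoidal batch severity multiplier
#'   (0 = off, the default).
#' @param seed Root random seed; per-animal substreams are derived from it.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_batches = 21, pigs_per_batch = 64,
                       n_sires = 60, dams_per_sire = 4,
                       trait_h2 = c(susceptibility = 0.3, appetite = 0.3,
                                    growth = 0.3),
                       genetic_corr = default_genetic_corr(),
                       baseline_fi_intercept = 1.4,
                       baseline_fi_slope = 0.015,
                       baseline_dur_mean = 65,
                       fi_noise_sd = 0.38, dur_noise_sd = 6,
                       episode_rate = 1.2,
                       episode_depth_range = c(0.3, 1),
                       episode_length_range = c(3, 12),
                       treatment_severity_threshold = 2.5,
                       mortality_severity_threshold = 7.08,
                       finishing_age_span = c(70, 181),
                       quarantine_entry_age = 21,
                       spike_rate = 0.002, missing_rate = 0.01,
                       seasonality = 0, seed = 1) {
  cfg <- as.list(environment())
  if (n_batches < 1 || pigs_per_batch < 1) stop_config("need at least one batch of one pig")
  if (n_sires < 1 || dams_per_sire < 1) stop_config("need at least one sire and dam")
  need <- c("susceptibility", "appetite", "growth")
  if (!all(need %in% names(trait_h2))) {
    stop_config("trait_h2 must name ", paste(need, collapse = ", "))
  }
  if (any(trait_h2 < 0 | trait_h2 > 1)) stop_config("heritabilities must lie in [0, 1]")
  gc <- as.matrix(genetic_corr)
  if (!isTRUE(all.equal(gc, t(gc))) || any(abs(diag(gc) - 1) > 1e-8)) {
    stop_config("genetic_corr must be symmetric with unit diagonal")
  }
  if (min(eigen(gc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop_config("genetic_corr must be positive semi-definite")
  }
  if (any(episode_depth_range < 0 | episode_depth_range > 1)) {
    stop_config("episode_depth_range must lie within [0, 1]")
  }
  if (finishing_age_span[1] >= finishing_age_span[2]) {
    stop_config("finishing_age_span must satisfy start < end")
  }
  structure(cfg, class = "sim_config")
}

#' Default genetic correlations among the latent traits
#'
#' Susceptible animals eat less and grow slower; appetite and growth are
#' positively related — the structure needed for resilience phenotypes to
#' correlate genetically with mortality and growth.
#' @return 3x3 correlation matrix (susceptibility, appetite, growth).
#' @export
default_genetic_corr <- function() {
  m <- matrix(c(1, -0.3, -0.4,
                -0.3, 1, 0.4,
                -0.4, 0.4, 1), 3, 3,
              dimnames = rep(list(c("susceptibility", "appetite", "growth")), 2))
  m
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Disease-challenge simulation config\n",
    "  %d batches x %d pigs (%d sires x %d dams each)\n",
    "  finishing ages %d-%d; FI %.2f + %.3f kg/d per day; duration mean %.0f min\n",
    "  episodes %.2f/100d, depth %.2f-%.2f, plateau %d-%d d; trt > %.1f, death > %.1f\n",
    "  h2: susceptibility %.2f, appetite %.2f, growth %.2f; seed %d\n"),
    x$n_batches, x$pigs_per_batch, x$n_sires, x$dams_per_sire,
    x$finishing_age_span[1], x$finishing_age_span[2],
    x$baseline_fi_intercept, x$baseline_fi_slope, x$baseline_dur_mean,
    x$episode_rate, x$episode_depth_range[1], x$episode_depth_range[2],
    x$episode_length_range[1], x$episode_length_range[2],
    x$treatment_severity_threshold, x$mortality_severity_threshold,
    x$trait_h2[["susceptibility"]], x$trait_h2[["appetite"]],
    x$trait_h2[["growth"]], x$seed))
  invisible(x)
}
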