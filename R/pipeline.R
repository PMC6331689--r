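#' Run the full resilience-phenotyping pipeline
#'
#' Orchestrates simulate (or load) -> clean -> growth -> resilience traits
#' -> production traits -> genetic parameters, writes every output table to
#' \code{out_dir} as CSV, and records a run manifest (configuration hash,
#' package version, row counts, cleaning/filter tallies). Identical
#' configurations produce identical outputs.
#'
#' @param config List with elements
#'   \describe{
#'     \item{simulate}{a [sim_config()], or \code{NULL} with
#'       \code{input_dir} naming a directory of [write_cohort()]-style CSVs;}
#'     \item{input_dir}{data-mode input directory (ignored in simulate mode);}
#'     \item{out_dir}{output directory;}
#'     \item{fi_cap, impute_window, tau, min_days}{cleaning/trait settings
#'       (defaults 5, 5, 0.05, 60);}
#'     \item{loess_span, loess_degree}{growth-curve settings (0.75, 2);}
#'     \item{genetics}{\code{NULL} to skip variance components, or a list
#'       with \code{traits} (character vector for univariate fits),
#'       \code{pairs} (list of trait pairs for bivariate fits),
#'       \code{fixed_finishing}, \code{fixed_entry} (fixed-effect sets).}
#'   }
#' @return Invisibly, a list with all in-memory tables, fitted lines,
#'   variance estimates and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_defaults(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  ## -- stage: data
  if (!is.null(cfg$simulate)) {
    log_stage("[simulate] %d batches x %d pigs, seed %d",
              cfg$simulate$n_batches, cfg$simulate$pigs_per_batch,
              cfg$simulate$seed)
    cohort <- simulate_cohort(cfg$simulate)
  } else {
    if (is.null(cfg$input_dir)) {
      stop_config("config needs either a simulate block or input_dir")
    }
    cohort <- tryCatch(read_cohort(cfg$input_dir), error = function(e) {
      stop_validation("feed_records stage: cannot load inputs: ",
                      conditionMessage(e))
    })
  }

  ## -- stage: feed_records
  cleaned <- clean_daily(cohort$daily, cap = cfg$fi_cap,
                         window = cfg$impute_window)
  log_stage("[feed_records] capped %d, imputed %d, unfilled %d",
            cleaned$report$n_capped, cleaned$report$n_imputed,
            cleaned$report$n_unfilled)

  ## -- stage: growth_model
  growth <- fit_growth_curves(cohort$weights, span = cfg$loess_span,
                              degree = cfg$loess_degree)
  adg <- phase_adg_table(growth$curves, cohort$animals, cleaned$records)
  log_stage("[growth_model] %d curves (%d linear fallback)",
            length(growth$curves),
            sum(vapply(growth$curves, function(g) g$method == "linear", TRUE)))

  ## -- stage: resilience_traits
  res <- resilience_table(cleaned$records, cohort$animals, cohort$treatments,
                          tau = cfg$tau, min_days = cfg$min_days)
  log_stage("[resilience_traits] %d/%d animals eligible",
            sum(!is.na(res$phenotypes$rmse_fi)), nrow(res$phenotypes))

  ## -- stage: production_traits
  prod <- production_table(cleaned$records, growth$daily, cohort$animals,
                           adg, cohort$carcass)

  ## -- stage: genetic_inference
  estimates <- NULL
  if (!is.null(cfg$genetics)) {
    estimates <- pipeline_genetics(cfg, cohort, res$phenotypes, prod)
    log_stage("[genetic_inference] %d models fit", nrow(estimates))
  }

  ## -- outputs
  phen <- merge(res$phenotypes, prod, by = "animal_id", sort = TRUE)
  tables <- list(animals = cohort$animals, daily_clean = cleaned$records,
                 adg = adg, daily_weights = growth$daily,
                 resilience = res$phenotypes, production = prod,
                 phenotypes = phen)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(cfg$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(estimates)) {
    utils::write.csv(estimates, file.path(cfg$out_dir, "estimates.csv"),
                     row.names = FALSE)
  }
  lines_json <- lapply(res$lines, function(l) {
    list(channel = l$channel, tau = l$tau, intercept = l$intercept,
         slope = l$slope, n_days = l$n)
  })
  jsonlite::write_json(lines_json, file.path(cfg$out_dir, "quantile_lines.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("resilipig")),
    config_hash = config_hash(cfg),
    cleaning = unclass(cleaned$report),
    rows = lapply(tables, nrow),
    n_models = if (is.null(estimates)) 0L else nrow(estimates))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(tables,
              list(lines = res$lines, estimates = estimates,
                   cohort = cohort, manifest = manifest,
                   out_dir = cfg$out_dir)))
}

pipeline_defaults <- function(config) {
  cfg <- config
  cfg$fi_cap <- cfg$fi_cap %||% 5
  cfg$impute_window <- cfg$impute_window %||% 5
  cfg$tau <- cfg$tau %||% 0.05
  cfg$min_days <- cfg$min_days %||% 60
  cfg$loess_span <- cfg$loess_span %||% 0.75
  cfg$loess_degree <- cfg$loess_degree %||% 2
  cfg$out_dir <- cfg$out_dir %||% tempfile("resilipig_run_")
  if (!is.null(cfg$genetics)) {
    g <- cfg$genetics
    g$traits <- g$traits %||% c("rmse_fi", "rmse_dur", "qr_fi", "qr_dur",
                                "mortality", "trt180")
    g$pairs <- g$pairs %||% list(c("qr_fi", "mortality"))
    g$fixed_entry <- g$fixed_entry %||% c("batch", "quarantine_entry_age")
    g$fixed_finishing <- g$fixed_finishing %||% c("batch", "fin_start_age", "pen")
    cfg$genetics <- g
  }
  cfg
}

## Fit the configured univariate and bivariate animal models on the merged
## phenotype table using the pedigree A matrix (entry-model fixed effects
## for mortality/treatment traits, finishing fixed effects otherwise).
pipeline_genetics <- function(cfg, cohort, resilience, production) {
  g <- cfg$genetics
  phen <- merge(resilience, production, by = "animal_id", sort = TRUE)
  m <- match(phen$animal_id, cohort$animals$animal_id)
  phen$quarantine_entry_age <- cohort$animals$quarantine_entry_age[m]
  if (!"batch" %in% names(phen)) phen$batch <- cohort$animals$batch[m]
  A <- pedigree_A(cohort$pedigree)
  entry_traits <- c("mortality", "trt", "trt180")
  fx <- function(tr) if (tr %in% entry_traits) g$fixed_entry else g$fixed_finishing
  rows <- list()
  for (tr in g$traits) {
    fit <- tryCatch(reml_univariate(tr, phen, A, fixed = fx(tr)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- data.frame(
      trait1 = tr, trait2 = NA, kind = fit$kind, n = fit$n,
      sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e, sigma_a12 = NA,
      h2_1 = fit$h2, h2_2 = NA, r_g = NA,
      se_h2_1 = fit$se_h2, se_h2_2 = NA, se_r_g = NA,
      loglik = fit$loglik, converged = fit$converged)
  }
  for (pr in g$pairs) {
    fixed <- unique(c(fx(pr[1]), fx(pr[2])))
    fit <- tryCatch(reml_bivariate(pr, phen, A, fixed = fixed),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- data.frame(
      trait1 = pr[1], trait2 = pr[2], kind = fit$kind, n = fit$n,
      sigma2_a = fit$sigma2_a[1], sigma2_e = fit$sigma2_e[1],
      sigma_a12 = fit$sigma_a12,
      h2_1 = fit$h2[1], h2_2 = fit$h2[2], r_g = fit$r_g,
      se_h2_1 = fit$se_h2[[1]], se_h2_2 = fit$se_h2[[2]],
      se_r_g = fit$se_r_g, loglik = fit$loglik, converged = fit$converged)
  }
  do.call(rbind, rows)
}

config_hash <- function(cfg) {
  norm <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  norm <- lapply(norm, function(x) if (inherits(x, "sim_config")) unclass(x) else x)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(norm, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Summarise a pipeline run as cohort-level report tables
#'
#' Builds the standard report shapes: per-batch counts with mortality
#' percentage and resilience-trait means; a whole-cohort trait summary
#' (count, mean, SD, median, min, max); and, when variance components were
#' estimated, a genetic-parameter table with heritabilities on the diagonal
#' position and genetic correlations listed per trait pair.
#'
#' @param run A [run_pipeline()] result, or a run directory containing its
#'   CSV outputs.
#' @param cohort Optional cohort (for batch/death information) when
#'   \code{run} is a directory.
#' @return List of data frames \code{by_batch}, \code{traits},
#'   \code{genetics} (the last \code{NULL} without estimates).
#' @export
summary_report <- function(run, cohort = NULL) {
  if (is.character(run)) {
    dirp <- run
    run <- list(
      resilience = utils::read.csv(file.path(dirp, "resilience.csv")),
      production = utils::read.csv(file.path(dirp, "production.csv")),
      estimates = if (file.exists(file.path(dirp, "estimates.csv")))
        utils::read.csv(file.path(dirp, "estimates.csv")) else NULL,
      cohort = cohort %||%
        list(animals = utils::read.csv(file.path(dirp, "animals.csv"))))
  }
  animals <- run$cohort$animals
  res <- merge(run$resilience, animals[, c("animal_id", "batch")],
               by = "animal_id")
  by_batch <- do.call(rbind, lapply(split(res, res$batch), function(d) {
    data.frame(batch = d$batch[1], count = nrow(d),
               mortality_pct = 100 * mean(d$mortality),
               trt = mean(d$trt, na.rm = TRUE),
               trt180 = mean(d$trt180, na.rm = TRUE),
               rmse_fi = mean(d$rmse_fi, na.rm = TRUE),
               rmse_dur = mean(d$rmse_dur, na.rm = TRUE),
               qr_fi = mean(d$qr_fi, na.rm = TRUE),
               qr_dur = mean(d$qr_dur, na.rm = TRUE))
  }))
  rownames(by_batch) <- NULL

  phen <- merge(run$resilience, run$production, by = "animal_id")
  trait_cols <- c("mortality", "trt", "trt180", "rmse_fi", "rmse_dur",
                  "qr_fi", "qr_dur", "nur_adg", "fin_adg", "adfi", "fcr",
                  "rfi", "cwt", "drs", "lyld", "cbf", "cld")
  trait_cols <- intersect(trait_cols, names(phen))
  traits <- do.call(rbind, lapply(trait_cols, function(tc) {
    v <- phen[[tc]][!is.na(phen[[tc]])]
    data.frame(trait = tc, n = length(v), mean = mean(v),
               sd = stats::sd(v), median = stats::median(v),
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  }))

  list(by_batch = by_batch, traits = traits, genetics = run$estimates)
}
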