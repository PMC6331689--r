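#' Simulate a natural disease-challenge cohort
#'
#' Generates a wean-to-finish cohort with the statistical structure the
#' downstream analysis assumes, so the whole pipeline can be validated
#' without any external data. The generative model:
#'
#' \itemize{
#'   \item Latent breeding values for susceptibility, appetite and growth
#'     are drawn on a half-sib sire/dam pedigree from a multivariate normal
#'     with the configured genetic covariance (additive variance =
#'     heritability on a unit-phenotypic-variance scale); offspring receive
#'     mid-parent plus Mendelian sampling. Environmental deviations are
#'     independent across traits.
#'   \item Illness episodes arrive per animal as a Poisson process whose
#'     rate scales with realised susceptibility; each episode has a plateau
#'     depth (fractional intake drop, deeper for susceptible animals) and
#'     length, with 2-day onset and recovery ramps. Severity = depth x
#'     plateau length (lost feed-days). Severity above the treatment
#'     threshold emits an individual treatment; above the mortality
#'     threshold the animal dies mid-episode and its records truncate.
#'   \item Daily feed intake in finishing is a linear baseline in age
#'     (shifted by appetite) times one minus the active episode depth, plus
#'     noise; feeder duration is intake divided by an animal-specific
#'     intake rate plus noise, so off-feed days depress both channels.
#'   \item Body weight integrates a growth rate that scales with the growth
#'     latent and drops with active episodes; weighings occur every 21 days
#'     with 1 kg measurement noise; carcass traits are generated for
#'     survivors.
#' }
#'
#' Per-animal random substreams are keyed by animal index, so an identical
#' configuration (including seed) reproduces the cohort byte for byte, and
#' the Poisson count uses an inverse-CDF draw from a pre-drawn episode pool,
#' so raising the episode rate only appends episodes.
#'
#' @param config A [sim_config()].
#' @return Object of class \code{challenge_cohort}: list of data frames
#'   \code{animals}, \code{daily}, \code{weights}, \code{treatments},
#'   \code{pedigree}, \code{truth} (breeding values and latent phenotypes),
#'   \code{carcass}, plus the \code{config}.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_batches = 2, seed = 42))
#' mean(!is.na(cohort$animals$death_age))   # realised mortality
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_batches * cfg$pigs_per_batch
  if (n < 1) stop_config("zero pigs requested")

  ped <- sim_pedigree(cfg, n)
  truth <- sim_breeding_values(cfg, ped)

  rate_mean <- (cfg$baseline_fi_intercept +
                  cfg$baseline_fi_slope * diff(cfg$finishing_age_span) / 2) /
               cfg$baseline_dur_mean

  animals <- vector("list", n); daily <- vector("list", n)
  weights <- vector("list", n); treatments <- vector("list", n)
  carcass <- vector("list", n)

  pig_rows <- match(sprintf("P%05d", seq_len(n)), truth$animal_id)
  for (i in seq_len(n)) {
    res <- with_seed(substream_seed(cfg$seed, i),
                     sim_one_pig(cfg, i, truth[pig_rows[i], ], rate_mean))
    animals[[i]] <- res$animal
    daily[[i]] <- res$daily
    weights[[i]] <- res$weights
    treatments[[i]] <- res$treatments
    carcass[[i]] <- res$carcass
  }

  out <- list(animals = do.call(rbind, animals),
              daily = canonical_daily(do.call(rbind, daily)),
              weights = do.call(rbind, weights),
              treatments = do.call(rbind, Filter(Negate(is.null), treatments)) %||%
                data.frame(animal_id = character(0), age = numeric(0),
                           reason = character(0)),
              pedigree = ped,
              truth = truth,
              carcass = do.call(rbind, Filter(Negate(is.null), carcass)),
              genotypes = NULL,
              config = cfg)
  if (is.null(out$treatments)) {
    out$treatments <- data.frame(animal_id = character(0), age = numeric(0),
                                 reason = character(0))
  }
  rownames(out$animals) <- rownames(out$weights) <- NULL
  class(out) <- "challenge_cohort"
  out
}

sim_pedigree <- function(cfg, n) {
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  dams <- sprintf("D%03d", seq_len(cfg$n_sires * cfg$dams_per_sire))
  dam_sire <- rep(seq_len(cfg$n_sires), each = cfg$dams_per_sire)
  pigs <- sprintf("P%05d", seq_len(n))
  asg <- with_seed(substream_seed(cfg$seed, 0), {
    s <- sample.int(cfg$n_sires, n, replace = TRUE)
    d <- (s - 1) * cfg$dams_per_sire + sample.int(cfg$dams_per_sire, n, replace = TRUE)
    list(s = s, d = d)
  })
  rbind(
    data.frame(id = sires, sire = NA_character_, dam = NA_character_,
               role = "sire"),
    data.frame(id = dams, sire = NA_character_, dam = NA_character_,
               role = "dam"),
    data.frame(id = pigs, sire = sires[asg$s], dam = dams[asg$d],
               role = "pig"))
}

sim_breeding_values <- function(cfg, ped) {
  h2 <- cfg$trait_h2[c("susceptibility", "appetite", "growth")]
  Sg <- diag(sqrt(h2)) %*% as.matrix(cfg$genetic_corr) %*% diag(sqrt(h2))
  ev <- eigen(Sg, symmetric = TRUE)
  Sg_half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  draw_mvn <- function(k, scale = 1) {
    matrix(stats::rnorm(3 * k), k, 3) %*% (Sg_half * sqrt(scale))
  }
  founders <- ped$role != "pig"
  nf <- sum(founders); np <- sum(!founders)
  bv <- matrix(0, nrow(ped), 3,
               dimnames = list(ped$id, c("susceptibility", "appetite", "growth")))
  with_seed(substream_seed(cfg$seed, nrow(ped) + 1), {
    bv[founders, ] <- draw_mvn(nf)
    sidx <- match(ped$sire[!founders], ped$id)
    didx <- match(ped$dam[!founders], ped$id)
    bv[!founders, ] <- 0.5 * (bv[sidx, ] + bv[didx, ]) + draw_mvn(np, 0.5)
  })
  env <- with_seed(substream_seed(cfg$seed, nrow(ped) + 2), {
    sweep(matrix(stats::rnorm(nrow(ped) * 3), ncol = 3), 2, sqrt(1 - h2), `*`)
  })
  val <- bv + env
  data.frame(animal_id = ped$id, role = ped$role,
             bv_susceptibility = bv[, 1], bv_appetite = bv[, 2],
             bv_growth = bv[, 3],
             susceptibility = val[, 1], appetite = val[, 2],
             growth = val[, 3])
}

## One pig's life course; runs inside its own RNG substream.
sim_one_pig <- function(cfg, i, tr, rate_mean) {
  id <- sprintf("P%05d", i)
  batch <- (i - 1) %/% cfg$pigs_per_batch + 1
  pen <- sprintf("B%02d-%d", batch, (i - 1) %% cfg$pigs_per_batch %/% 16 + 1)
  entry <- cfg$quarantine_entry_age + sample.int(8, 1) - 4   # 18..25 d
  fin <- cfg$finishing_age_span
  slaughter_age <- fin[2]

  season <- 1 + cfg$seasonality * sin(2 * pi * batch / max(cfg$n_batches, 1))

  ## --- episode pool (fixed size; count via inverse CDF so a larger rate
  ## only appends episodes, never reshuffles existing ones)
  pool_n <- 60L
  u_count <- stats::runif(1)
  onset_u <- stats::runif(pool_n)
  depth_z <- stats::rnorm(pool_n)
  len_u <- stats::runif(pool_n)
  lifespan <- slaughter_age - entry
  lam <- cfg$episode_rate / 100 * lifespan * exp(0.8 * tr$susceptibility) * season
  n_ep <- min(stats::qpois(u_count, max(lam, 0)), pool_n)
  ep <- NULL
  if (n_ep > 0) {
    k <- seq_len(n_ep)
    depth <- pmin(pmax(0.55 + 0.18 * (depth_z[k] + 0.9 * tr$susceptibility),
                       cfg$episode_depth_range[1]), cfg$episode_depth_range[2])
    len <- cfg$episode_length_range[1] +
      round(len_u[k] * diff(cfg$episode_length_range))
    ep <- data.frame(onset = entry + floor(onset_u[k] * lifespan),
                     depth = depth, len = len,
                     severity = depth * len)
  }

  ## --- death and treatments
  death_age <- NA_real_
  if (!is.null(ep)) {
    fatal <- ep$severity > cfg$mortality_severity_threshold
    if (any(fatal)) {
      cand <- ep$onset[fatal] + ceiling(ep$len[fatal] / 2)
      death_age <- min(cand)
      ep <- ep[ep$onset < death_age, , drop = FALSE]
      if (!nrow(ep)) ep <- NULL
    }
  }
  last_age <- if (is.na(death_age)) slaughter_age else min(death_age, slaughter_age)
  trts <- NULL
  if (!is.null(ep)) {
    tre <- ep[ep$severity > cfg$treatment_severity_threshold, , drop = FALSE]
    if (nrow(tre)) {
      t_age <- pmin(tre$onset + 1, last_age)
      trts <- data.frame(animal_id = id, age = t_age, reason = "illness")
    }
  }

  ## multiplicative intake depression from all active episodes, with 2-day ramps
  depression <- function(ages) {
    m <- rep(1, length(ages))
    if (is.null(ep)) return(m)
    for (j in seq_len(nrow(ep))) {
      o <- ep$onset[j]; L <- ep$len[j]; dep <- ep$depth[j]
      rel <- ages - o
      f <- numeric(length(ages))
      f[rel >= 0 & rel < 2] <- rel[rel >= 0 & rel < 2] / 2
      f[rel >= 2 & rel < 2 + L] <- 1
      rec <- rel - (2 + L)
      f[rec >= 0 & rec < 2] <- 1 - rec[rec >= 0 & rec < 2] / 2
      m <- m * (1 - dep * f)
    }
    m
  }

  ## --- daily feed records (finishing only)
  daily <- NULL
  if (last_age > fin[1]) {
    ages <- seq(fin[1], min(last_age, fin[2]) - 1)
    base <- (cfg$baseline_fi_intercept + 0.2 * tr$appetite) +
      cfg$baseline_fi_slope * (ages - fin[1])
    fi <- pmax(base * depression(ages) + stats::rnorm(length(ages), 0, cfg$fi_noise_sd), 0)
    rate <- rate_mean * exp(stats::rnorm(1, 0, 0.12))
    dur <- pmax(fi / rate + stats::rnorm(length(ages), 0, cfg$dur_noise_sd), 0)
    lost <- stats::runif(length(ages)) < cfg$missing_rate
    fi[lost] <- NA_real_; dur[lost] <- NA_real_   # feeder outage: day recorded empty
    spike <- stats::runif(length(ages)) < cfg$spike_rate
    fi[spike & !lost] <- stats::runif(sum(spike & !lost), 6, 8)
    daily <- data.frame(animal_id = id, age = ages, fi = fi, dur = dur)
    if (!nrow(daily)) daily <- NULL
  }

  ## --- growth and weighings
  all_ages <- seq(entry, last_age)
  adg_base <- 0.25 + 0.75 * pmin((all_ages - entry) / 120, 1)
  adg <- adg_base * (1 + 0.15 * tr$growth) * (1 - 0.8 * (1 - depression(all_ages)))
  wt <- 6.5 + cumsum(adg)
  weigh_ages <- unique(c(seq(entry, last_age, by = 21), last_age))
  wobs <- wt[match(weigh_ages, all_ages)] + stats::rnorm(length(weigh_ages), 0, 1)
  weights <- data.frame(animal_id = id, age = weigh_ages,
                        weight = pmax(wobs, 1))

  ## --- carcass (survivors only)
  carc <- NULL
  survived <- is.na(death_age)
  if (survived) {
    lw <- wt[length(wt)]
    cwt <- 0.78 * lw + stats::rnorm(1, 0, 1.5)
    cbf <- max(stats::rnorm(1, 18 - 1.2 * tr$growth, 3.3), 7)
    cld <- max(stats::rnorm(1, 60.7 + 2 * tr$growth, 5.5), 40)
    carc <- data.frame(animal_id = id, cwt = cwt, cbf = cbf, cld = cld,
                       live_weight = lw,
                       ultrasound_bf = cbf + stats::rnorm(1, 0, 1))
  }

  list(animal = data.frame(animal_id = id, batch = sprintf("B%02d", batch),
                           pen = pen, quarantine_entry_age = entry,
                           finishing_start_age = fin[1],
                           death_age = death_age,
                           slaughtered = survived,
                           slaughter_age = if (survived) slaughter_age else NA_real_,
                           live_weight_at_slaughter = if (survived)
                             wt[length(wt)] else NA_real_),
       daily = daily, weights = weights, treatments = trts, carcass = carc)
}

#' @export
print.challenge_cohort <- function(x, ...) {
  n <- nrow(x$animals)
  mort <- mean(!is.na(x$animals$death_age))
  cat(sprintf(paste0("Simulated disease-challenge cohort: %d pigs in %d batches\n",
                     "  %d daily records, %d weighings, %d treatments, mortality %.1f%%\n"),
              n, length(unique(x$animals$batch)), nrow(x$daily),
              nrow(x$weights), nrow(x$treatments), 100 * mort))
  if (!is.null(x$genotypes)) {
    cat(sprintf("  genotypes: %d animals x %d SNPs\n",
                nrow(x$genotypes), ncol(x$genotypes)))
  }
  invisible(x)
}

#' Gene-drop SNP genotypes through the simulated pedigree
#'
#' Founders receive haplotypes at Hardy-Weinberg proportions with allele
#' frequencies uniform on \code{maf_range}; descendants inherit one allele
#' per parent per marker (free recombination), so genomic relationships are
#' consistent with pedigree relationships in expectation.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_snps Number of markers. 0 yields an empty matrix.
#' @param maf_range Founder allele-frequency interval, inside (0, 0.5].
#' @return The cohort with a \code{genotypes} dosage matrix (animals x
#'   SNPs, rownames = animal ids) attached.
#' @export
simulate_genotypes <- function(cohort, n_snps = 1000, maf_range = c(0.05, 0.5)) {
  stopifnot(inherits(cohort, "challenge_cohort"))
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_config("maf_range must lie within (0, 0.5]")
  }
  ped <- cohort$pedigree
  if (is.null(ped)) stop_validation("cohort has no pedigree")
  n <- nrow(ped)
  if (n_snps == 0) {
    cohort$genotypes <- matrix(numeric(0), n, 0, dimnames = list(ped$id, NULL))
    return(cohort)
  }
  cohort$genotypes <- with_seed(substream_seed(cohort$config$seed, n + 3), {
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    H1 <- matrix(NA_integer_, n, n_snps)
    H2 <- matrix(NA_integer_, n, n_snps)
    founder <- is.na(ped$sire) & is.na(ped$dam)
    nf <- sum(founder)
    H1[founder, ] <- matrix(stats::rbinom(nf * n_snps, 1, rep(p, each = nf)), nf)
    H2[founder, ] <- matrix(stats::rbinom(nf * n_snps, 1, rep(p, each = nf)), nf)
    sidx <- match(ped$sire, ped$id)
    didx <- match(ped$dam, ped$id)
    for (i in which(!founder)) {
      pick_s <- stats::runif(n_snps) < 0.5
      pick_d <- stats::runif(n_snps) < 0.5
      H1[i, ] <- ifelse(pick_s, H1[sidx[i], ], H2[sidx[i], ])
      H2[i, ] <- ifelse(pick_d, H1[didx[i], ], H2[didx[i], ])
    }
    M <- H1 + H2
    dimnames(M) <- list(ped$id, sprintf("SNP%05d", seq_len(n_snps)))
    M
  })
  cohort
}

#' Write a simulated cohort to delimited text files
#'
#' Writes \code{animals.csv}, \code{daily.csv}, \code{weights.csv},
#' \code{treatments.csv}, \code{pedigree.csv}, \code{truth.csv},
#' \code{carcass.csv}, optionally \code{genotypes.csv}, and the
#' configuration as \code{config.yaml}.
#'
#' @param cohort A \code{challenge_cohort}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "challenge_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("animals", "daily", "weights", "treatments", "pedigree",
               "truth", "carcass")) {
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(cohort$genotypes) && ncol(cohort$genotypes)) {
    g <- data.frame(animal_id = rownames(cohort$genotypes),
                    cohort$genotypes, check.names = FALSE)
    utils::write.csv(g, file.path(dir, "genotypes.csv"), row.names = FALSE)
  }
  cfg <- cohort$config
  cfg$genetic_corr <- as.vector(cfg$genetic_corr)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort back from [write_cohort()] output
#'
#' @param dir Directory written by [write_cohort()].
#' @return A \code{challenge_cohort} (without genotypes unless present).
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop_validation("missing input file: ", f)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  out <- list(animals = rd("animals"), daily = rd("daily"),
              weights = rd("weights"), treatments = rd("treatments"),
              pedigree = rd("pedigree"), truth = rd("truth"),
              carcass = rd("carcass"), genotypes = NULL, config = NULL)
  gf <- file.path(dir, "genotypes.csv")
  if (file.exists(gf)) {
    g <- utils::read.csv(gf, check.names = FALSE)
    out$genotypes <- as.matrix(g[, -1, drop = FALSE])
    rownames(out$genotypes) <- g$animal_id
  }
  class(out) <- "challenge_cohort"
  out
}
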