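test_that("identical configurations reproduce the cohort exactly", {
  cfg <- sim_config(n_batches = 3, pigs_per_batch = 40, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$daily, c2$daily)
  expect_identical(c1$animals, c2$animals)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(sim_config(n_batches = 3, pigs_per_batch = 40, seed = 78))
  expect_false(identical(c1$daily, c3$daily))
})

test_that("without stressors and noise every pig sits on its linear baseline", {
  cfg <- sim_config(n_batches = 1, pigs_per_batch = 20, episode_rate = 0,
                    fi_noise_sd = 0, dur_noise_sd = 0, spike_rate = 0,
                    missing_rate = 0, seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$treatments), 0)
  expect_true(all(is.na(co$animals$death_age)))
  for (id in co$animals$animal_id[1:5]) {
    d <- co$daily[co$daily$animal_id == id, ]
    ## second differences of an exact line vanish
    expect_lt(max(abs(diff(diff(d$fi)))), 1e-12)
    expect_equal(diff(d$fi)[1], cfg$baseline_fi_slope, tolerance = 1e-12)
  }
})

test_that("record truncation respects death ages", {
  co <- simulate_cohort(sim_config(n_batches = 4, pigs_per_batch = 50,
                                   mortality_severity_threshold = 5, seed = 3))
  dead <- co$animals[!is.na(co$animals$death_age), ]
  expect_gt(nrow(dead), 0)
  for (i in seq_len(nrow(dead))) {
    d <- co$daily[co$daily$animal_id == dead$animal_id[i], ]
    if (nrow(d)) expect_lt(max(d$age), dead$death_age[i])
  }
  early <- dead[dead$death_age <= co$config$finishing_age_span[1], ]
  if (nrow(early)) {
    expect_equal(nrow(co$daily[co$daily$animal_id %in% early$animal_id, ]), 0)
  }
})

test_that("raising the episode rate never reduces realised off-feed days", {
  base <- function(rate) {
    sim_config(n_batches = 2, pigs_per_batch = 60, episode_rate = rate,
               fi_noise_sd = 0, dur_noise_sd = 0, spike_rate = 0,
               missing_rate = 0, seed = 13)
  }
  offfeed <- function(cfg) {
    co <- simulate_cohort(cfg)
    fin <- cfg$finishing_age_span
    ## with zero noise, a day below the appetite-adjusted linear baseline
    ## is an episode day
    n_off <- 0
    for (id in co$animals$animal_id) {
      d <- co$daily[co$daily$animal_id == id, ]
      if (!nrow(d)) next
      tr <- co$truth[co$truth$animal_id == id, ]
      bl <- (cfg$baseline_fi_intercept + 0.2 * tr$appetite) +
        cfg$baseline_fi_slope * (d$age - fin[1])
      n_off <- n_off + sum(d$fi < bl - 1e-9)
    }
    n_off
  }
  rates <- c(0, 0.8, 1.6, 3.2)
  counts <- vapply(lapply(rates, base), offfeed, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
})

test_that("a heritable latent trait realises the expected sire-family variance", {
  ## 200 sire families of 20: between-sire variance of a trait with
  ## heritability h2 is h2/4 of the (unit) phenotypic variance
  cfg <- sim_config(n_batches = 10, pigs_per_batch = 400, n_sires = 200,
                    dams_per_sire = 20, seed = 17)
  ped <- resilipig:::sim_pedigree(cfg, 4000)
  truth <- resilipig:::sim_breeding_values(cfg, ped)
  tp <- truth[truth$role == "pig", ]
  sire <- ped$sire[match(tp$animal_id, ped$id)]
  fam <- split(tp$susceptibility, sire)
  k <- mean(lengths(fam))
  msb <- var(vapply(fam, mean, numeric(1))) * k
  msw <- mean(vapply(fam, var, numeric(1)))
  s2_sire <- (msb - msw) / k
  ns <- length(fam)
  se <- sqrt(2 * msb^2 / (ns - 1) + 2 * msw^2 / (ns * (k - 1))) / k
  expect_lt(abs(s2_sire - cfg$trait_h2[["susceptibility"]] / 4), 3 * se)
})

test_that("switching off heritability removes the family signal in off-feed days", {
  ## with no heritable susceptibility (or appetite) the split-half
  ## correlation of half-sib family means of QR_FI is pure noise
  gc <- diag(3)
  dimnames(gc) <- rep(list(c("susceptibility", "appetite", "growth")), 2)
  cfg <- sim_config(n_batches = 8, pigs_per_batch = 256, n_sires = 128,
                    dams_per_sire = 4,
                    trait_h2 = c(susceptibility = 0, appetite = 0,
                                 growth = 0.3),
                    genetic_corr = gc, seed = 19)
  co <- simulate_cohort(cfg)
  cl <- clean_daily(co$daily)
  res <- resilience_table(cl$records, co$animals, co$treatments)
  p <- res$phenotypes
  sire <- co$pedigree$sire[match(p$animal_id, co$pedigree$id)]
  keep <- !is.na(p$qr_fi)
  qr <- p$qr_fi[keep]; sire <- sire[keep]
  set.seed(19)
  half <- as.logical(ave(seq_along(qr), sire,
                         FUN = function(i) seq_along(i) %% 2))
  m1 <- tapply(qr[half], sire[half], mean)
  m2 <- tapply(qr[!half], sire[!half], mean)
  common <- intersect(names(m1), names(m2))
  expect_lt(abs(cor(m1[common], m2[common])), 0.15)
})

test_that("the default cohort realises the intended mortality", {
  co <- simulate_cohort(sim_config(seed = 1))
  mort <- mean(!is.na(co$animals$death_age))
  expect_lt(abs(mort - 0.26), 0.05)
})

test_that("cohorts round-trip through CSV unchanged", {
  dir <- tempfile("cohort_")
  co <- simulate_cohort(sim_config(n_batches = 1, pigs_per_batch = 15, seed = 23))
  co <- simulate_genotypes(co, n_snps = 20)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$daily$fi, co$daily$fi, tolerance = 1e-12)
  expect_equal(back$animals$animal_id, co$animals$animal_id)
  expect_equal(unname(back$genotypes), unname(co$genotypes))
  expect_identical(rownames(back$genotypes), rownames(co$genotypes))
  unlink(dir, recursive = TRUE)
})
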