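test_that("ADFI and FCR follow their defining arithmetic", {
  expect_equal(adfi(rep(2.2, 100)), 2.2)
  expect_equal(adfi(c(1, 2, 3)), 2)
  expect_equal(adfi(c(1, NA, 3)), 2)
  expect_true(is.na(adfi(c(NA, NA))))

  expect_equal(fcr(rep(2, 100), 30, 110), 200 / 80)  # 2.5
  expect_warning(z <- fcr(rep(2, 10), 50, 50))
  expect_true(is.na(z))
  ## identity: FCR * gain = total feed
  set.seed(51)
  fi <- runif(90, 1.5, 3)
  f <- fcr(fi, 32.4, 118.9)
  expect_equal(f * (118.9 - 32.4), sum(fi), tolerance = 1e-10)
})

test_that("RFI is a centred residual orthogonal to its covariates", {
  set.seed(52)
  n <- 120
  d <- data.frame(
    batch = sample(c("B1", "B2", "B3"), n, TRUE),
    pen = sample(c("p1", "p2"), n, TRUE),
    fin_start_age = runif(n, 65, 75),
    avg_weight = runif(n, 60, 90),
    fin_adg = runif(n, 0.6, 1.1),
    ultrasound_bf = runif(n, 8, 25))
  d$adfi <- 1 + 0.01 * d$avg_weight + 0.8 * d$fin_adg + rnorm(n, 0, 0.2)
  r <- rfi(d)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  for (v in c("fin_adg", "ultrasound_bf")) {
    z <- scale(d[[v]])[, 1]
    expect_lt(abs(sum(scale(r)[, 1] * z)) / n, 1e-8)
  }

  ## exact linear dependence -> all residuals vanish
  d2 <- d
  d2$adfi <- 2 + 0.02 * d2$avg_weight^0.75 + 0.5 * d2$fin_adg +
    0.01 * d2$ultrasound_bf
  expect_lt(max(abs(rfi(d2))), 1e-10)

  ## identical covariates -> centring limit
  d3 <- d
  d3[c("avg_weight", "fin_adg", "ultrasound_bf")] <- list(75, 0.9, 15)
  d3$batch <- "B1"; d3$pen <- "p1"; d3$fin_start_age <- 70
  expect_equal(suppressMessages(rfi(d3)), d3$adfi - mean(d3$adfi),
               tolerance = 1e-10)
})

test_that("dressing proportion divides carcass by live weight with guards", {
  expect_equal(dressing(78, 100), 0.78)
  expect_equal(dressing(93.77, 118.9), 93.77 / 118.9)
  expect_warning(dressing(100, 100))
  expect_error(dressing(50, 0), class = "resilipig_validation_error")
})

test_that("lean yield evaluates the carcass polynomial and is backfat-driven", {
  expect_identical(lean_yield(0, 0), 68.1863)
  ## value at the cohort-mean carcass measurements sits near the cohort
  ## mean lean yield (the polynomial is nonlinear, so not exactly)
  expect_lt(abs(lean_yield(17.96, 60.69) - 60.92), 1.5)

  ## monotone decreasing in backfat over the observed carcass range
  for (cld in c(41.5, 60, 81)) {
    v <- lean_yield(seq(7.5, 33.5, by = 0.5), cld)
    expect_true(all(diff(v) < 0))
  }

  ## simulated carcass table: correlation with backfat close to -0.98
  set.seed(53)
  cbf <- pmax(rnorm(800, 17.96, 3.87), 7.5)
  cld <- pmax(rnorm(800, 60.69, 6.14), 41.5)
  expect_lt(cor(lean_yield(cbf, cld), cbf), -0.95)

  expect_error(lean_yield(-1, 50), class = "resilipig_validation_error")
})

test_that("the production table wires phases, carcass and RFI together", {
  set.seed(54)
  ids <- sprintf("p%d", 1:30)
  daily <- do.call(rbind, lapply(ids, function(id) {
    age <- 70:169
    make_daily(id, age, pmax(1.2 + 0.013 * (age - 70) + rnorm(100, 0, 0.3), 0))
  }))
  weights <- do.call(rbind, lapply(ids, function(id) {
    age <- seq(21, 180, by = 21)
    data.frame(animal_id = id, age = age,
               weight = 6 + 0.62 * (age - 21) + rnorm(length(age), 0, 1))
  }))
  animals <- data.frame(animal_id = ids, batch = rep(c("B1", "B2"), 15),
                        pen = rep(c("x", "y"), each = 15),
                        quarantine_entry_age = 21, finishing_start_age = 70,
                        death_age = NA, slaughter_age = 180)
  carcass <- data.frame(animal_id = ids, cwt = rnorm(30, 93, 5),
                        cbf = runif(30, 10, 25), cld = runif(30, 50, 70),
                        live_weight = rnorm(30, 119, 5),
                        ultrasound_bf = runif(30, 10, 25))
  gr <- fit_growth_curves(weights)
  adg <- phase_adg_table(gr$curves, animals, daily)
  prod <- production_table(daily, gr$daily, animals, adg, carcass)
  expect_equal(nrow(prod), 30)
  expect_true(all(prod$adfi > 0))
  expect_equal(prod$drs, prod$cwt / carcass$live_weight[match(prod$animal_id, carcass$animal_id)])
  expect_equal(mean(prod$rfi, na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(prod$lyld, lean_yield(prod$cbf, prod$cld))
})
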