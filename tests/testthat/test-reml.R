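test_that("small-n restricted likelihood matches a dense grid-search oracle", {
  set.seed(71)
  n <- 30
  ped <- make_halfsib_pedigree(6, 5)
  A <- pedigree_A(ped)
  pigs <- grepl("^P", A$ids)
  K <- A$values[pigs, pigs]
  y <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * 0.6 +
    rnorm(n, 0, 0.8) + 2
  d <- data.frame(animal_id = A$ids[pigs], y = y)
  fit <- reml_univariate("y", d, A)

  X <- matrix(1, n, 1)
  grid <- expand.grid(s2a = seq(0.001, 2.5, length.out = 150),
                      s2e = seq(0.05, 2.5, length.out = 150))
  ll <- mapply(function(a, e) oracle_restricted_ll(a, e, K, y, X),
               grid$s2a, grid$s2e)
  ## the optimiser must attain (or slightly beat) the grid maximum
  expect_gte(fit$loglik, max(ll) - 1e-4)
  ## and the dense formula agrees with the eigen formula at the optimum
  expect_equal(fit$loglik,
               oracle_restricted_ll(fit$sigma2_a, fit$sigma2_e, K, y, X),
               tolerance = 1e-6)
})

test_that("REML estimates are invariant to phenotype shifts and row order", {
  set.seed(72)
  ped <- make_halfsib_pedigree(30, 8)
  A <- pedigree_A(ped)
  d <- sim_traits_on_A(A, matrix(0.3), matrix(0.7), seed = 5)
  d <- d[grepl("^P", d$animal_id), ]
  f1 <- reml_univariate("y1", d, A)
  d2 <- d; d2$y1 <- d2$y1 + 100
  f2 <- reml_univariate("y1", d2, A)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-6)
  f3 <- reml_univariate("y1", d[sample(nrow(d)), ], A)
  expect_equal(f1$h2, f3$h2, tolerance = 1e-6)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
})

test_that("a null trait yields a near-zero heritability estimate", {
  ped <- make_halfsib_pedigree(40, 10)
  A <- pedigree_A(ped)
  h2s <- vapply(1:3, function(s) {
    d <- sim_traits_on_A(A, matrix(1e-12), matrix(1), seed = 100 + s)
    d <- d[grepl("^P", d$animal_id), ]
    reml_univariate("y1", d, A)$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.08)
})

test_that("fixed effects are absorbed before variance estimation", {
  set.seed(73)
  ped <- make_halfsib_pedigree(25, 8)
  A <- pedigree_A(ped)
  d <- sim_traits_on_A(A, matrix(0.4), matrix(0.6), seed = 7)
  d <- d[grepl("^P", d$animal_id), ]
  d$batch <- sample(c("b1", "b2", "b3", "b4"), nrow(d), TRUE)
  d$entry <- runif(nrow(d), 18, 25)
  shift <- c(b1 = 0, b2 = 3, b3 = -2, b4 = 5)
  d$y_shift <- d$y1 + shift[d$batch] + 0.2 * d$entry
  ## the shift is an exact linear function of the fixed effects, so fitting
  ## the shifted trait with them equals fitting the raw trait with them
  f0 <- reml_univariate("y1", d, A, fixed = c("batch", "entry"))
  f1 <- reml_univariate("y_shift", d, A, fixed = c("batch", "entry"))
  expect_equal(f1$h2, f0$h2, tolerance = 1e-6)
  expect_equal(f1$sigma2_a, f0$sigma2_a, tolerance = 1e-6)
  expect_equal(length(coef(f1)), 1 + 3 + 1)  # intercept + 3 batch contrasts + slope
})

test_that("bivariate REML recovers itself, the null, and matches univariate", {
  ped <- make_halfsib_pedigree(60, 8)
  A <- pedigree_A(ped)
  pigs <- grepl("^P", A$ids)

  ## independent genetic effects: r_g near zero on average
  rgs <- vapply(1:3, function(s) {
    d <- sim_traits_on_A(A, diag(c(0.3, 0.3)), diag(c(0.7, 0.7)),
                         seed = 200 + s)
    d <- d[pigs, ]
    reml_bivariate(c("y1", "y2"), d, A)$r_g
  }, numeric(1))
  expect_lt(mean(abs(rgs)), 0.25)

  ## trait-1 components from the bivariate fit match the univariate fit
  Sg <- matrix(c(0.3, 0.15, 0.15, 0.3), 2)
  d <- sim_traits_on_A(A, Sg, diag(c(0.7, 0.7)), seed = 300)[pigs, ]
  bi <- reml_bivariate(c("y1", "y2"), d, A)
  un <- reml_univariate("y1", d, A)
  expect_equal(bi$h2[[1]], un$h2, tolerance = 0.03)
  expect_true(bi$converged)
  expect_true(abs(bi$r_g) <= 1)

  ## accepted objective values never increase (best-so-far trace)
  expect_true(all(diff(bi$trace) <= 1e-12))

  ## two copies of one trait drive the genetic correlation to 1
  d2 <- d; d2$y2 <- d2$y1
  same <- reml_bivariate(c("y1", "y2"), d2, A)
  expect_gte(same$r_g, 0.98)
})

test_that("a shared eigendecomposition reproduces the per-fit result", {
  ped <- make_halfsib_pedigree(25, 8)
  A <- pedigree_A(ped)
  pigs <- grepl("^P", A$ids)
  Apig <- structure(list(kind = A$kind, ids = A$ids[pigs],
                         values = A$values[pigs, pigs]),
                    class = "relationship_matrix")
  dec <- reml_decompose(Apig)
  d <- sim_traits_on_A(A, matrix(0.25), matrix(0.75), seed = 11)[pigs, ]
  f1 <- reml_univariate("y1", d, Apig)
  f2 <- reml_univariate("y1", d, Apig, decomp = dec)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})
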