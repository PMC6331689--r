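test_that("pedigree A reproduces textbook relationships", {
  ped <- data.frame(id = c("f1", "f2", "f3", "kid1", "kid2", "half"),
                    sire = c(NA, NA, NA, "f1", "f1", "f1"),
                    dam = c(NA, NA, NA, "f2", "f2", "f3"))
  A <- pedigree_A(ped)
  V <- A$values
  expect_equal(V[c("f1", "f2", "f3"), c("f1", "f2", "f3")], diag(3),
               ignore_attr = TRUE)
  expect_equal(V["f1", "kid1"], 0.5)        # parent-offspring
  expect_equal(V["kid1", "kid2"], 0.5)      # full sibs
  expect_equal(V["kid1", "half"], 0.25)     # half sibs
  expect_equal(unname(diag(V)), rep(1, 6))  # no inbreeding here

  ## an offspring of two full sibs is inbred: diagonal 1 + 0.5*0.5
  ped2 <- rbind(ped, data.frame(id = "inbred", sire = "kid1", dam = "kid2"))
  expect_equal(pedigree_A(ped2)$values["inbred", "inbred"], 1.25)

  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(pedigree_A(cyc), class = "resilipig_validation_error")
})

test_that("tabular A matches the gene-drop expectation on a random pedigree", {
  set.seed(61)
  n <- 20
  ped <- data.frame(id = sprintf("a%02d", 1:n), sire = NA_character_,
                    dam = NA_character_)
  for (i in 7:n) {
    ped$sire[i] <- ped$id[sample(1:(i - 1), 1)]
    ped$dam[i] <- ped$id[sample(1:(i - 1), 1)]
  }
  ## a parent pair must be two distinct animals
  same <- !is.na(ped$sire) & ped$sire == ped$dam
  ped$dam[same] <- ped$id[1]
  A <- pedigree_A(ped)
  drop <- oracle_genedrop_A(ped, n_rep = 10000, seed = 2)
  expect_lt(max(abs(A$values - drop)), 0.02)
})

test_that("VanRaden G behaves like an identity-by-state relationship", {
  set.seed(62)
  n <- 200; m <- 5000
  p <- runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(M) <- sprintf("g%03d", 1:n)
  G <- vanraden_G(M)
  expect_equal(mean(diag(G$values)), 1, tolerance = 0.05)
  expect_lt(abs(mean(G$values[upper.tri(G$values)])), 0.02)

  ## dosage mean of founders ~ 2p within 3 binomial SE (per marker; a few
  ## of 5000 independent markers may exceed 3 SE by chance)
  se <- sqrt(2 * p * (1 - p) / n)
  expect_gt(mean(abs(colMeans(M) - 2 * p) < 3 * se), 0.99)

  ## duplicated individual: off-diagonal equals its diagonal
  M2 <- rbind(M, dup = M[1, ])
  G2 <- vanraden_G(M2)
  expect_equal(G2$values["g001", "dup"], G2$values["g001", "g001"],
               tolerance = 1e-10)

  expect_error(vanraden_G(matrix(2, 5, 4)), class = "resilipig_config_error")
  expect_error(vanraden_G(matrix(3, 2, 2)), class = "resilipig_validation_error")
})

test_that("gene-dropped genotypes give genomic relationships near pedigree", {
  cfg <- sim_config(n_batches = 4, pigs_per_batch = 50, n_sires = 10,
                    dams_per_sire = 3, seed = 9)
  co <- simulate_genotypes(simulate_cohort(cfg), n_snps = 800)
  G <- vanraden_G(co$genotypes)
  ped <- co$pedigree
  pigs <- ped$id[ped$role == "pig"]
  ## half sibs: same sire, different dam
  sires <- ped$sire[match(pigs, ped$id)]
  dams <- ped$dam[match(pigs, ped$id)]
  hs <- which(outer(sires, sires, "==") & outer(dams, dams, "!=") &
                upper.tri(matrix(0, length(pigs), length(pigs))), arr.ind = TRUE)
  idx <- match(pigs, G$ids)
  vals <- G$values[cbind(idx[hs[, 1]], idx[hs[, 2]])]
  ## G is centred at the observed allele frequencies, which shifts every
  ## pair downward relative to the pedigree base; the half-sib vs
  ## unrelated-pair contrast removes that shift
  un <- which(outer(sires, sires, "!=") & outer(dams, dams, "!=") &
                upper.tri(matrix(0, length(pigs), length(pigs))), arr.ind = TRUE)
  base <- mean(G$values[cbind(idx[un[, 1]], idx[un[, 2]])])
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - base - 0.25), 3 * se + 0.02)

  ## zero markers: empty matrix, cohort intact
  co0 <- simulate_genotypes(simulate_cohort(cfg), n_snps = 0)
  expect_equal(ncol(co0$genotypes), 0)
  expect_equal(co0$daily, simulate_cohort(cfg)$daily)

  expect_error(simulate_genotypes(co, maf_range = c(0, 0.6)),
               class = "resilipig_config_error")
})

test_that("H blending is exact in its degenerate limits and stays PSD", {
  ped <- make_halfsib_pedigree(20, 10)
  A <- pedigree_A(ped)
  ## no genotyped animals -> H = A
  Gempty <- structure(list(kind = "genomic-G", ids = character(0),
                           values = matrix(0, 0, 0)),
                      class = "relationship_matrix")
  expect_equal(blend_H(A, Gempty)$values, A$values)

  ## all genotyped, G = A, weight -> 1: H = A
  Gfull <- structure(list(kind = "genomic-G", ids = A$ids, values = A$values),
                     class = "relationship_matrix")
  expect_equal(blend_H(A, Gfull, weight = 1)$values, A$values,
               tolerance = 1e-10)

  ## genotyped subset from gene-dropped markers: PSD, difference from A
  ## concentrated on the genotyped block
  cfg <- sim_config(n_batches = 2, pigs_per_batch = 50, n_sires = 8,
                    dams_per_sire = 3, seed = 10)
  co <- simulate_genotypes(simulate_cohort(cfg), n_snps = 600)
  Ac <- pedigree_A(co$pedigree)
  gids <- co$pedigree$id[co$pedigree$role == "pig"][1:60]
  G <- vanraden_G(co$genotypes[gids, ])
  H <- blend_H(Ac, G)
  expect_gte(min(eigen(H$values, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  dif <- abs(H$values - Ac$values)
  g <- match(gids, H$ids)
  expect_gt(mean(dif[g, g]), mean(dif[-g, -g]))
})
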