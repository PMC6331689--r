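## Independent oracles and fixture builders used across the suite.

## Pointwise local regression oracle: tricube-weighted least squares at a
## single target point, neighbourhood = the floor(n * span) nearest points.
oracle_local_fit <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- min(floor(n * span), n)
  d <- abs(x - x0)
  dq <- sort(d)[q]
  w <- pmax(1 - (d / dq)^3, 0)^3
  X <- outer(x - x0, 0:degree, `^`)
  b <- solve(crossprod(X * w, X), crossprod(X * w, y))
  b[1]
}

## Brute-force pinball-loss minimum over all lines through pairs of points
## (every optimal basic solution of the quantile-regression LP is such a
## line). Only valid at small n.
oracle_pinball_min <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[i] - y[j]) / (x[i] - x[j])
    a <- y[i] - b * x[i]
    r <- y - a - b * x
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

## Textbook dense-matrix restricted log-likelihood (direct formula, no
## eigen tricks) for the grid-search REML oracle.
oracle_restricted_ll <- function(s2a, s2e, K, y, X) {
  n <- length(y)
  V <- s2a * K + diag(s2e, n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  p <- ncol(X)
  -0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

## Gene-drop estimate of expected additive relationships: drop unique
## founder alleles through the pedigree many times and count sharing.
oracle_genedrop_A <- function(ped, n_rep = 10000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  sidx <- match(ped$sire, ped$id)
  didx <- match(ped$dam, ped$id)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_rep)) {
    a1 <- a2 <- integer(n)
    nxt <- 1L
    for (i in seq_len(n)) {
      if (is.na(sidx[i])) { a1[i] <- nxt; nxt <- nxt + 1L }
      else a1[i] <- if (runif(1) < 0.5) a1[sidx[i]] else a2[sidx[i]]
      if (is.na(didx[i])) { a2[i] <- nxt; nxt <- nxt + 1L }
      else a2[i] <- if (runif(1) < 0.5) a1[didx[i]] else a2[didx[i]]
    }
    share <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
              outer(a2, a1, "==") + outer(a2, a2, "==")) / 2
    acc <- acc + share
  }
  acc / n_rep
}

## Half-sib pedigree: ns sires, noff offspring each, dams unknown.
make_halfsib_pedigree <- function(ns, noff) {
  rbind(
    data.frame(id = sprintf("S%04d", seq_len(ns)), sire = NA_character_,
               dam = NA_character_),
    data.frame(id = sprintf("P%05d", seq_len(ns * noff)),
               sire = rep(sprintf("S%04d", seq_len(ns)), each = noff),
               dam = NA_character_))
}

## Phenotypes with additive covariance Sg (per-trait additive variance on
## the diagonal) and unit residual complement, drawn on the A matrix.
sim_traits_on_A <- function(A, Sg, Se, seed, mu = 1) {
  set.seed(seed)
  nt <- nrow(Sg)
  L <- chol(A$values + diag(1e-8, length(A$ids)))
  a <- t(L) %*% matrix(rnorm(length(A$ids) * nt), ncol = nt) %*% chol(Sg)
  e <- matrix(rnorm(length(A$ids) * nt), ncol = nt) %*% chol(Se)
  Y <- mu + a + e
  d <- data.frame(animal_id = A$ids, Y)
  names(d)[-1] <- paste0("y", seq_len(nt))
  d
}

## Small deterministic daily-record fixture builder.
make_daily <- function(animal_id, age, fi, dur = fi * 30) {
  data.frame(animal_id = animal_id, age = age, fi = fi, dur = dur)
}
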