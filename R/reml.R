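#' Univariate animal-model REML via eigendecomposition
#'
#' Fits \eqn{y = Xb + a + e} with \eqn{a \sim N(0, K\sigma^2_a)},
#' \eqn{e \sim N(0, I\sigma^2_e)}, where K is a pedigree, genomic or blended
#' relationship matrix, by restricted maximum likelihood. With a single
#' relationship kernel the restricted likelihood profiles down to a
#' one-dimensional convex-like search over the variance ratio
#' \eqn{\lambda = \sigma^2_a / \sigma^2_e} after one eigendecomposition of
#' K, so the optimum is located essentially exactly. Heritability is
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}; standard errors come
#' from the inverse observed information of the restricted likelihood with a
#' delta-method step for \eqn{h^2}.
#'
#' @param trait Name of the response column in \code{data}.
#' @param data Data frame with \code{animal_id}, the trait, and any
#'   fixed-effect columns. Rows with missing trait or fixed effects are
#'   dropped.
#' @param relationship A \code{\link{pedigree_A}}, \code{\link{vanraden_G}}
#'   or \code{\link{blend_H}} object covering the phenotyped animals.
#' @param fixed Character vector of fixed-effect column names; non-numeric
#'   columns become factors. \code{NULL} fits an intercept only.
#' @param decomp Optional precomputed \code{\link{reml_decompose}} object;
#'   reused when the phenotyped animals match, which saves the
#'   eigendecomposition across traits on a common data set.
#' @return Object of class \code{animal_reml} with variance components,
#'   \code{h2}, standard errors, fixed-effect estimates, the restricted
#'   log-likelihood and a convergence flag.
#' @seealso [reml_bivariate()] for genetic correlations.
#' @export
reml_univariate <- function(trait, data, relationship, fixed = NULL,
                            decomp = NULL) {
  md <- reml_model_frame(trait, data, relationship, fixed)
  n <- length(md$y); p <- ncol(md$X)
  if (n < 10) stop_validation("too few phenotyped animals for REML (n = ", n, ")")
  ed <- reml_subset_decomp(decomp, relationship, md$ids)
  yt <- crossprod(ed$U, md$y)
  Xt <- crossprod(ed$U, md$X)
  d <- ed$d

  prof <- function(loglam) uni_restricted_ll(exp(loglam), d, yt, Xt)
  opt <- stats::optimize(function(l) -prof(l), c(-12, 12), tol = 1e-9)
  ## the ratio can sit at the lower boundary (h2 -> 0)
  ll0 <- prof(-12)
  if (ll0 >= -opt$objective - 1e-10) {
    loglam <- -12; ll <- ll0; boundary <- TRUE
  } else {
    loglam <- opt$minimum; ll <- -opt$objective; boundary <- FALSE
  }
  lam <- exp(loglam)
  w <- 1 / (lam * d + 1)
  gls <- uni_gls(w, yt, Xt)
  sigma2_e <- gls$rss / (n - p)
  sigma2_a <- lam * sigma2_e
  if (boundary) sigma2_a <- 0
  h2 <- sigma2_a / (sigma2_a + sigma2_e)

  ## observed information in (sigma2_a, sigma2_e)
  llfun <- function(th) uni_restricted_ll_direct(th[1], th[2], d, yt, Xt)
  se <- reml_se(llfun, c(sigma2_a, sigma2_e),
                h2_grad = function(th) {
                  s <- sum(th)
                  c(th[2] / s^2, -th[1] / s^2)
                })

  beta <- gls$beta
  names(beta) <- colnames(md$X)
  structure(list(traits = trait, kind = relationship$kind, n = n,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 h2 = h2, se_sigma2_a = se$se_par[1], se_sigma2_e = se$se_par[2],
                 se_h2 = se$se_fun, beta = beta, loglik = ll,
                 converged = TRUE, boundary = boundary,
                 fixed = fixed %||% character(0)),
            class = "animal_reml")
}

#' Bivariate animal-model REML via the canonical transformation
#'
#' Fits a two-trait animal model with unstructured 2x2 additive-genetic
#' (\eqn{G_0}) and residual (\eqn{R_0}) covariance matrices on the animals
#' with both traits observed. Because both traits share one relationship
#' matrix and one fixed-effects design, rotating the data by the
#' eigenvectors of K decouples the restricted likelihood into independent
#' 2x2 blocks, one per eigenvalue, which makes each evaluation linear in n.
#' \eqn{G_0} and \eqn{R_0} are parameterised by log-Cholesky factors, which
#' keeps them positive definite and the genetic correlation
#' \eqn{r_g = \sigma_{a12} / \sqrt{\sigma^2_{a1}\sigma^2_{a2}}} inside
#' \eqn{[-1, 1]} throughout the maximisation.
#'
#' @param traits Character vector of two response column names.
#' @param data,relationship,fixed,decomp As in [reml_univariate()].
#' @param maxit Maximum optimiser iterations. Default 4000.
#' @return \code{animal_reml} object with per-trait variance components and
#'   heritabilities, the additive covariance \code{sigma_a12}, \code{r_g}
#'   and standard errors.
#' @export
reml_bivariate <- function(traits, data, relationship, fixed = NULL,
                           decomp = NULL, maxit = 4000) {
  stopifnot(length(traits) == 2)
  md <- reml_model_frame(traits, data, relationship, fixed)
  n <- length(md$ids); p <- ncol(md$X)
  if (n < 10) stop_validation("too few jointly phenotyped animals (n = ", n, ")")
  ed <- reml_subset_decomp(decomp, relationship, md$ids)
  Yt <- crossprod(ed$U, md$Y)          # n x 2
  Xt <- crossprod(ed$U, md$X)
  d <- ed$d

  ## start values from univariate fits and the phenotypic correlation
  uni <- lapply(1:2, function(t) {
    o <- stats::optimize(function(l) -uni_restricted_ll(exp(l), d, Yt[, t], Xt),
                         c(-12, 12), tol = 1e-7)
    lam <- exp(o$minimum)
    w <- 1 / (lam * d + 1)
    g <- uni_gls(w, Yt[, t], Xt)
    s2e <- g$rss / (n - p)
    c(a = max(lam * s2e, 1e-4 * stats::var(md$Y[, t])), e = s2e)
  })
  rp <- stats::cor(md$Y[, 1], md$Y[, 2]) * 0.5
  G0 <- matrix(c(uni[[1]]["a"], rp * sqrt(uni[[1]]["a"] * uni[[2]]["a"]),
                 rp * sqrt(uni[[1]]["a"] * uni[[2]]["a"]), uni[[2]]["a"]), 2)
  R0 <- matrix(c(uni[[1]]["e"], rp * sqrt(uni[[1]]["e"] * uni[[2]]["e"]),
                 rp * sqrt(uni[[1]]["e"] * uni[[2]]["e"]), uni[[2]]["e"]), 2)

  trace_env <- new.env(); trace_env$best <- numeric(0)
  obj <- function(theta) {
    v <- bi_neg2_restricted_ll(theta, d, Yt, Xt)
    if (!is.finite(v)) v <- 1e12
    b <- trace_env$best
    trace_env$best <- c(b, if (length(b)) min(v, b[length(b)]) else v)
    v
  }
  par0 <- c(chol_to_theta(G0), chol_to_theta(R0))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  theta <- fit$par
  G0 <- theta_to_cov(theta[1:3]); R0 <- theta_to_cov(theta[4:6])
  r_g <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  h2 <- diag(G0) / (diag(G0) + diag(R0))

  llfun <- function(th) -0.5 * bi_neg2_restricted_ll(th, d, Yt, Xt)
  derived <- function(th) {
    G <- theta_to_cov(th[1:3]); R <- theta_to_cov(th[4:6])
    c(h2_1 = G[1, 1] / (G[1, 1] + R[1, 1]),
      h2_2 = G[2, 2] / (G[2, 2] + R[2, 2]),
      r_g = G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
  }
  se <- reml_se_multi(llfun, theta, derived)

  structure(list(traits = traits, kind = relationship$kind, n = n,
                 sigma2_a = diag(G0), sigma2_e = diag(R0),
                 sigma_a12 = G0[1, 2], sigma_e12 = R0[1, 2],
                 G0 = G0, R0 = R0, h2 = h2, r_g = r_g,
                 se_h2 = se[c("h2_1", "h2_2")], se_r_g = se[["r_g"]],
                 loglik = -0.5 * fit$value, converged = fit$convergence == 0,
                 trace = trace_env$best, fixed = fixed %||% character(0)),
            class = "animal_reml")
}

## ---- internals ------------------------------------------------------------

reml_model_frame <- function(traits, data, relationship, fixed) {
  stopifnot(inherits(relationship, "relationship_matrix"))
  assert_cols(data, c("animal_id", traits, fixed), "phenotype data")
  keep <- rep(TRUE, nrow(data))
  for (v in c(traits, fixed)) keep <- keep & !is.na(data[[v]])
  keep <- keep & data$animal_id %in% relationship$ids
  d <- data[keep, , drop = FALSE]
  if (anyDuplicated(d$animal_id)) stop_validation("one phenotype row per animal required")
  X <- reml_design(d, fixed)
  Y <- as.matrix(d[, traits, drop = FALSE])
  list(ids = as.character(d$animal_id), X = X, Y = Y,
       y = if (length(traits) == 1) as.numeric(Y[, 1]) else NULL)
}

reml_design <- function(d, fixed) {
  if (is.null(fixed) || !length(fixed)) {
    return(matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)")))
  }
  for (f in fixed) if (!is.numeric(d[[f]])) d[[f]] <- factor(d[[f]])
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(fixed, collapse = "+"))), d)
  ## drop aliased columns so the GLS cross-product stays invertible
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

#' Eigendecompose a relationship matrix for reuse across REML fits
#'
#' @param relationship A \code{relationship_matrix}.
#' @return List with \code{ids}, eigenvalues \code{d} (floored at 1e-10) and
#'   eigenvectors \code{U}.
#' @export
reml_decompose <- function(relationship) {
  e <- eigen(relationship$values, symmetric = TRUE)
  list(ids = relationship$ids, d = pmax(e$values, 1e-10), U = e$vectors)
}

reml_subset_decomp <- function(decomp, relationship, ids) {
  if (!is.null(decomp) && identical(decomp$ids, ids)) return(decomp)
  idx <- match(ids, relationship$ids)
  K <- relationship$values[idx, idx, drop = FALSE]
  e <- eigen(K, symmetric = TRUE)
  list(ids = ids, d = pmax(e$values, 1e-10), U = e$vectors)
}

uni_gls <- function(w, yt, Xt) {
  XtW <- Xt * w
  XX <- crossprod(XtW, Xt)
  beta <- solve(XX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  list(beta = as.numeric(beta), rss = sum(w * r^2), XX = XX)
}

## restricted log-likelihood profiled over sigma2_e, as a function of the
## variance ratio lambda = sigma2_a / sigma2_e
uni_restricted_ll <- function(lam, d, yt, Xt) {
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (lam * d + 1)
  gls <- uni_gls(w, yt, Xt)
  s2e <- gls$rss / (n - p)
  ## log|V| = n log s2e + sum(log(lam*d + 1));
  ## log|X'V^-1 X| = log|Xt' W Xt| - p log s2e;  y'Py = (n - p) at the
  ## profiled s2e, so the s2e exponents collapse to (n - p).
  -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) - sum(log(w)) +
            determinant(gls$XX, logarithm = TRUE)$modulus)
}

## unprofiled restricted log-likelihood at explicit variance components
uni_restricted_ll_direct <- function(s2a, s2e, d, yt, Xt) {
  if (s2a < 0 || s2e <= 0) return(-Inf)
  n <- length(yt); p <- ncol(Xt)
  v <- s2a * d + s2e
  w <- 1 / v
  gls <- uni_gls(w, yt, Xt)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) +
            determinant(gls$XX, logarithm = TRUE)$modulus + gls$rss)
}

chol_to_theta <- function(S) {
  L <- t(chol(S + diag(1e-10, 2)))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

theta_to_cov <- function(th) {
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  tcrossprod(L)
}

## -2 * restricted log-likelihood of the rotated bivariate model; V_i =
## d_i * G0 + R0 per eigenvalue, shared fixed-effect design per trait.
bi_neg2_restricted_ll <- function(theta, d, Yt, Xt) {
  G0 <- theta_to_cov(theta[1:3]); R0 <- theta_to_cov(theta[4:6])
  n <- length(d); p <- ncol(Xt)
  v11 <- d * G0[1, 1] + R0[1, 1]
  v12 <- d * G0[1, 2] + R0[1, 2]
  v22 <- d * G0[2, 2] + R0[2, 2]
  det_i <- v11 * v22 - v12^2
  if (any(det_i <= 0) || any(v11 <= 0)) return(Inf)
  a11 <- v22 / det_i; a22 <- v11 / det_i; a12 <- -v12 / det_i

  M11 <- crossprod(Xt * a11, Xt); M22 <- crossprod(Xt * a22, Xt)
  M12 <- crossprod(Xt * a12, Xt)
  M <- rbind(cbind(M11, M12), cbind(M12, M22))
  rhs <- c(crossprod(Xt, a11 * Yt[, 1] + a12 * Yt[, 2]),
           crossprod(Xt, a12 * Yt[, 1] + a22 * Yt[, 2]))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), rhs))
  r1 <- Yt[, 1] - Xt %*% beta[1:p]
  r2 <- Yt[, 2] - Xt %*% beta[p + 1:p]
  quad <- sum(a11 * r1^2 + 2 * a12 * r1 * r2 + a22 * r2^2)
  sum(log(det_i)) + 2 * sum(log(diag(ch))) + quad + 2 * (n - p) * log(2 * pi)
}

## SEs from the numeric observed information; fun maps parameters to the
## restricted log-likelihood, h2_grad gives the analytic gradient of the
## derived quantity for the delta method.
reml_se <- function(llfun, par, h2_grad) {
  H <- num_hessian(llfun, par)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(par), length(par)))
  se_par <- suppressWarnings(sqrt(diag(V)))
  g <- h2_grad(par)
  se_fun <- suppressWarnings(sqrt(drop(t(g) %*% V %*% g)))
  list(se_par = se_par, se_fun = se_fun)
}

reml_se_multi <- function(llfun, theta, derived) {
  H <- num_hessian(llfun, theta)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  J <- num_jacobian(derived, theta)
  S <- J %*% V %*% t(J)
  out <- suppressWarnings(sqrt(diag(S)))
  names(out) <- names(derived(theta))
  out
}

num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  h <- h %||% pmax(abs(x), 1e-3) * 1e-4
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

num_jacobian <- function(f, x, h = NULL) {
  h <- h %||% pmax(abs(x), 1e-3) * 1e-5
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    J[, i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  J
}

## ---- methods --------------------------------------------------------------

#' @export
print.animal_reml <- function(x, ...) {
  if (length(x$traits) == 1) {
    cat(sprintf("Animal model REML (%s), trait %s, n = %d\n",
                x$kind, x$traits, x$n))
    cat(sprintf("  sigma2_a = %.4g  sigma2_e = %.4g\n", x$sigma2_a, x$sigma2_e))
    cat(sprintf("  h2 = %.3f (SE %.3f)%s\n", x$h2, x$se_h2,
                if (isTRUE(x$boundary)) "  [boundary: additive variance at 0]" else ""))
  } else {
    cat(sprintf("Bivariate animal model REML (%s), traits %s / %s, n = %d\n",
                x$kind, x$traits[1], x$traits[2], x$n))
    cat(sprintf("  h2 = %.3f (SE %.3f), %.3f (SE %.3f)\n",
                x$h2[1], x$se_h2[1], x$h2[2], x$se_h2[2]))
    cat(sprintf("  r_g = %.3f (SE %.3f)\n", x$r_g, x$se_r_g))
    if (!x$converged) cat("  ** did not converge **\n")
  }
  cat(sprintf("  restricted logLik = %.4f\n", x$loglik))
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  print(object)
  if (length(object$beta)) {
    cat("Fixed effects:\n")
    print(object$beta)
  }
  invisible(object)
}

#' @export
coef.animal_reml <- function(object, ...) object$beta

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$loglik, df = if (length(object$traits) == 1) 2 else 6,
            class = "logLik")
}
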