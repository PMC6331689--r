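#' Pedigree additive relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix A by the tabular (recursive)
#' method: animals are processed parents-first; the relationship of animal i
#' to an older animal j is the average of j's relationships to i's parents,
#' and i's diagonal is 1 plus half the relationship between its parents.
#' Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param pedigree Data frame with columns \code{id}, \code{sire},
#'   \code{dam}; unknown parents \code{NA}. Need not be sorted.
#' @return Object of class \code{relationship_matrix}: list with \code{kind
#'   = "pedigree-A"}, \code{ids}, and the symmetric matrix \code{values}.
#' @export
pedigree_A <- function(pedigree) {
  assert_cols(pedigree, c("id", "sire", "dam"), "pedigree")
  ped <- pedigree
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (any(duplicated(ped$id))) stop_validation("duplicate ids in pedigree")

  ## topological order: repeatedly emit animals whose parents are placed
  n <- nrow(ped)
  placed <- character(0)
  remaining <- ped
  order_ids <- character(0)
  while (nrow(remaining)) {
    ## a parent that is unknown (NA), already placed, or absent from the
    ## table (treated as an unknown founder) does not block its offspring
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed |
              !(remaining$sire %in% ped$id)) &
             (is.na(remaining$dam) | remaining$dam %in% placed |
              !(remaining$dam %in% ped$id))
    if (!any(ready)) stop_validation("pedigree contains a cycle")
    order_ids <- c(order_ids, remaining$id[ready])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ped <- ped[match(order_ids, ped$id), ]

  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  sidx <- match(ped$sire, ped$id)  # NA for unknown/outside parents
  didx <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- sidx[i]; d <- didx[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  orig <- as.character(pedigree$id)
  new_relationship(A[orig, orig, drop = FALSE], "pedigree-A")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = ZZ'/\sum_j 2 p_j (1 - p_j)} with \eqn{Z = M - P}, where M holds
#' allele dosages in \{0, 1, 2\}, and P is the matrix of twice the observed
#' allele frequencies. Monomorphic markers carry no information and are
#' excluded.
#'
#' @param M Dosage matrix, animals in rows (rownames = ids), markers in
#'   columns.
#' @return \code{relationship_matrix} of kind \code{"genomic-G"}.
#' @export
vanraden_G <- function(M) {
  M <- as.matrix(M)
  if (!all(M %in% c(0, 1, 2))) stop_validation("dosages must be 0, 1 or 2")
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_config("all markers are monomorphic; G undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / sum(2 * p * (1 - p))
  dimnames(G) <- list(rownames(M), rownames(M))
  new_relationship(G, "genomic-G")
}

#' Single-step blended relationship matrix H
#'
#' Combines the pedigree matrix A with a genomic matrix G over the genotyped
#' subset: G is first tuned (scaled and shifted) so its mean diagonal and
#' mean off-diagonal match the genotyped block of A, then blended as
#' \eqn{G_w = w G^* + (1 - w) A_{22}}, and the standard single-step identity
#' \deqn{H = A + \begin{bmatrix} A_{12}A_{22}^{-1}(G_w - A_{22})A_{22}^{-1}A_{21}
#'   & A_{12}A_{22}^{-1}(G_w - A_{22}) \\ (G_w - A_{22})A_{22}^{-1}A_{21}
#'   & G_w - A_{22} \end{bmatrix}}
#' replaces the genotyped block. If the blend is not positive semi-definite
#' the genomic weight is lowered stepwise with a warning.
#'
#' @param A Pedigree \code{relationship_matrix} covering all animals.
#' @param G Genomic \code{relationship_matrix} (ids a subset of A's).
#' @param weight Genomic weight w in (0, 1]. Default 0.95.
#' @return \code{relationship_matrix} of kind \code{"blended-H"}.
#' @export
blend_H <- function(A, G, weight = 0.95) {
  stopifnot(inherits(A, "relationship_matrix"),
            inherits(G, "relationship_matrix"))
  gid <- G$ids
  if (!all(gid %in% A$ids)) stop_validation("genotyped ids must be a subset of pedigree ids")
  if (!length(gid)) return(new_relationship(A$values, "blended-H"))
  Av <- A$values
  idx2 <- match(gid, A$ids)
  idx1 <- setdiff(seq_along(A$ids), idx2)
  A22 <- Av[idx2, idx2, drop = FALSE]
  Gv <- G$values
  ## tune G to A22 scale: solve mean(diag) and mean(offdiag) match
  tune <- function(Gv, A22) {
    md_g <- mean(diag(Gv)); mo_g <- mean(Gv[upper.tri(Gv)])
    md_a <- mean(diag(A22)); mo_a <- mean(A22[upper.tri(A22)])
    if (length(gid) < 2 || !is.finite(mo_g) || abs(md_g - mo_g) < 1e-12) {
      return(Gv)
    }
    beta <- (md_a - mo_a) / (md_g - mo_g)
    alpha <- md_a - beta * md_g
    alpha + beta * Gv
  }
  Gs <- tune(Gv, A22)
  w <- weight
  repeat {
    Gw <- w * Gs + (1 - w) * A22
    H <- Av
    D <- Gw - A22
    if (length(idx1)) {
      A22inv <- solve(A22)
      A12 <- Av[idx1, idx2, drop = FALSE]
      B <- A12 %*% A22inv
      H[idx1, idx1] <- Av[idx1, idx1] + B %*% D %*% t(B)
      H[idx1, idx2] <- A12 + B %*% D
      H[idx2, idx1] <- t(H[idx1, idx2])
    }
    H[idx2, idx2] <- Gw
    ev <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > -1e-8 || w <= 0.05) break
    w <- w - 0.15
    warning(sprintf("H not PSD; lowering genomic weight to %.2f", w))
  }
  new_relationship(H, "blended-H")
}

new_relationship <- function(values, kind) {
  values <- (values + t(values)) / 2
  structure(list(kind = kind, ids = rownames(values), values = values),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d animals, mean diagonal %.3f\n",
              x$kind, length(x$ids), mean(diag(x$values))))
  invisible(x)
}
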