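#' Centre SNP genotypes at observed allele frequencies
#'
#' @param M dosage matrix (animals x SNPs, entries 0/1/2, complete).
#' @return list with `Z` (centred matrix, `dosage - 2p`) and `p` (observed
#'   allele frequencies, column means over all genotyped animals divided
#'   by 2). Monomorphic columns trigger a warning and are retained; they
#'   contribute zeros.
#' @export
center_genotypes <- function(M) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("dosage matrix contains missing values; impute or filter first")
  p <- colMeans(M) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) retained; they contribute zero")
  }
  Z <- sweep(M, 2, 2 * p, "-")
  list(Z = Z, p = p)
}

#' SNP-variance scaling factor of the genomic relationship matrix
#'
#' The common prior variance ratio of SNP effects,
#' `(1 - w) / (2 sum p(1-p))`, where `w` is the proportion of additive
#' genetic variance treated as residual polygenic. `B` is this scalar times
#' the identity.
#'
#' @param p observed allele frequencies.
#' @param w residual polygenic proportion in `[0, 1)` (or 1 for the
#'   degenerate pedigree-only limit, giving 0).
#' @return the scalar diagonal value of `B`.
#' @export
build_B <- function(p, w) {
  stopifnot(w >= 0, w <= 1)
  den <- 2 * sum(p * (1 - p))
  if (den <= 0) stop("all SNPs are monomorphic; B is undefined")
  (1 - w) / den
}

#' Genomic relationship matrix with residual polygenic fraction
#'
#' `G = Z B Z' + w A_gg` with `B = b I` from [build_B()].
#'
#' @param Z centred genotype matrix of the genotyped animals.
#' @param b scalar from [build_B()].
#' @param w residual polygenic proportion.
#' @param A_gg pedigree relationship block of the genotyped animals.
#' @return symmetric matrix with the genotyped animals' labels.
#' @export
build_G <- function(Z, b, w, A_gg) {
  G <- tcrossprod(Z) * b + w * A_gg
  (G + t(G)) / 2
}

#' Single-step combined relationship matrix
#'
#' Assembles the joint covariance structure of breeding values of
#' non-genotyped and genotyped animals under single-step SNPBLUP:
#' the genotyped block is `G`, the cross block is
#' `A_ng A_gg^{-1} G`, and the non-genotyped block is
#' `A_nn - A_ng A_gg^{-1} A_gn + A_ng A_gg^{-1} G A_gg^{-1} A_gn`.
#' Equivalently `H^{-1} = A^{-1} + blockdiag(0, G^{-1} - A_gg^{-1})`;
#' both routes are implemented and agree to solver precision.
#'
#' @param part a [rel_partition()].
#' @param G genomic relationship matrix over the genotyped animals (same
#'   order as `part$genotyped`). Must be non-singular for the inverse
#'   route, which in practice requires a positive residual polygenic
#'   proportion `w`.
#' @param route `"blocks"` for the explicit block formulas, `"inverse"`
#'   to invert `H^{-1}`.
#' @return dense symmetric matrix over all animals, rows/columns ordered
#'   as `part$order` (non-genotyped first).
#' @export
assemble_H <- function(part, G, route = c("blocks", "inverse")) {
  route <- match.arg(route)
  ng <- part$nongenotyped
  g <- part$genotyped
  if (route == "blocks") {
    if (length(ng) == 0) {
      H <- G
      dimnames(H) <- list(g, g)
      return(H)
    }
    P <- solve_agg(part, t(part$A_ng))          # A_gg^{-1} A_gn, g x n
    H_ng <- t(P) %*% G                          # n x g
    H_nn <- part$A_nn - part$A_ng %*% P + t(P) %*% G %*% P
    H <- rbind(cbind(H_nn, H_ng), cbind(t(H_ng), G))
  } else {
    H <- solve(h_inverse(part, G))
  }
  H <- (H + t(H)) / 2
  dimnames(H) <- list(part$order, part$order)
  H
}

#' Inverse of the single-step relationship matrix
#'
#' `H^{-1} = A^{-1} + blockdiag(0, G^{-1} - A_gg^{-1})`, the form used in
#' the mixed-model equations. `A` is reassembled from the partition blocks.
#'
#' @inheritParams assemble_H
#' @param A_inv optional precomputed inverse of the full `A` in the
#'   partition's (non-genotyped first) order, to avoid refactorizing when
#'   several genotyped sets share a pedigree.
#' @return dense symmetric matrix ordered as `part$order`.
#' @export
h_inverse <- function(part, G, A_inv = NULL) {
  g <- part$genotyped
  n_n <- length(part$nongenotyped)
  if (is.null(A_inv)) {
    A <- rbind(cbind(part$A_nn, part$A_ng),
               cbind(t(part$A_ng), part$A_gg))
    A_inv <- chol2inv(chol(A))
  }
  G_inv <- tryCatch(chol2inv(chol(G)), error = function(e) {
    stop("G is numerically singular; use a residual polygenic ",
         "proportion w > 0")
  })
  Hi <- A_inv
  idx <- n_n + seq_along(g)
  Hi[idx, idx] <- Hi[idx, idx] + G_inv - chol2inv(chol(part$A_gg))
  Hi <- (Hi + t(Hi)) / 2
  dimnames(Hi) <- list(part$order, part$order)
  Hi
}
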