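#' Solve Henderson's mixed-model equations
#'
#' Fits the animal model
#' `y = Xb + Z J mu + Z u + W c + e`
#' with `u ~ MVN(0, K var_a)` over all pedigree animals, an optional
#' i.i.d. non-genetic maternal permanent environmental effect
#' `c ~ MVN(0, I var_c)` per dam, and `e ~ MVN(0, I var_e)`. The fixed
#' block holds the cell-means coding of the combined environmental factor
#' plus the J-factor covariate columns; the relationship structure enters
#' through its inverse `K^{-1}` (pedigree `A^{-1}` for pedigree BLUP, the
#' single-step `H^{-1}` for ssSNPBLUP).
#'
#' Rank-deficient fixed blocks (e.g. a single J-factor when every
#' phenotyped animal is genotyped, where the covariate is constant and
#' confounded with the general mean) are handled by dropping the aliased
#' trailing columns, emitting a warning that names them; dropped J
#' coefficients are flagged non-estimable and contribute nothing to the
#' breeding values.
#'
#' @param pheno data.frame with columns `animal`, `y`, `fixed` (combined
#'   environmental factor level) and optionally `dam` (maternal identifier).
#' @param K_inv inverse relationship matrix over all animals, with animal
#'   labels as dimnames; every phenotyped animal must appear.
#' @param varcomp list or named vector with `var_a`, `var_e`, and `var_c`
#'   (the latter required only when a `dam` column is present).
#' @param J optional covariate matrix (all animals x k, rownames = animal
#'   labels) from [jfactor_direct()] / [jfactor_efficient()]; `NULL` fits
#'   no genotype-mean regression.
#'
#' @return object of class `jf_solutions`: list with elements
#'   `fixed` (named vector), `j_coef` (named, `NA` where non-estimable),
#'   `j_estimable`, `u` (breeding values, all animals), `pe` (maternal
#'   permanent environmental effects, or `NULL`), `gebv`
#'   (`J %*% j_coef + u`, equal to `u` when no J is fitted), and
#'   `residual` (relative residual of the solved system).
#' @export
solve_mme <- function(pheno, K_inv, varcomp, J = NULL) {
  vc <- as.list(varcomp)
  stopifnot(is.numeric(vc$var_a), vc$var_a > 0,
            is.numeric(vc$var_e), vc$var_e > 0)
  animals <- rownames(K_inv)
  if (is.null(animals)) stop("K_inv must carry animal labels as dimnames")
  pheno$animal <- as.character(pheno$animal)
  if (!all(pheno$animal %in% animals)) {
    stop("phenotyped animals missing from K_inv: ",
         paste(utils::head(setdiff(pheno$animal, animals)), collapse = ", "))
  }
  n_a <- length(animals)
  ia <- match(pheno$animal, animals)
  nrec <- nrow(pheno)

  f <- droplevels(factor(pheno$fixed))
  X <- matrix(0, nrec, nlevels(f),
              dimnames = list(NULL, paste0("fx_", levels(f))))
  X[cbind(seq_len(nrec), as.integer(f))] <- 1
  k_j <- 0L
  if (!is.null(J)) {
    J <- as.matrix(J)
    if (is.null(rownames(J)) || !all(animals %in% rownames(J))) {
      stop("J must have rownames covering all animals in K_inv")
    }
    J <- J[animals, , drop = FALSE]
    if (is.null(colnames(J))) colnames(J) <- paste0("J", seq_len(ncol(J)))
    k_j <- ncol(J)
    Fmat <- cbind(X, J[ia, , drop = FALSE])
  } else {
    Fmat <- X
  }
  k_all <- ncol(Fmat)

  # detect and drop aliased fixed columns (minimum-rank constrained solve)
  qrF <- qr(Fmat)
  keep <- sort(qrF$pivot[seq_len(qrF$rank)])
  dropped <- colnames(Fmat)[setdiff(seq_len(k_all), keep)]
  j_estimable <- rep(TRUE, k_j)
  if (k_j > 0) names(j_estimable) <- colnames(J)
  if (length(dropped) > 0) {
    warning("aliased fixed-effect columns dropped (confounded): ",
            paste(dropped, collapse = ", "))
    if (k_j > 0) j_estimable[colnames(J) %in% dropped] <- FALSE
    Fmat <- Fmat[, keep, drop = FALSE]
  }
  k <- ncol(Fmat)

  use_pe <- !is.null(pheno$dam)
  if (use_pe) {
    stopifnot(is.numeric(vc$var_c), vc$var_c > 0)
    dams <- sort(unique(as.character(pheno$dam)))
    idd <- match(as.character(pheno$dam), dams)
    n_d <- length(dams)
  } else {
    n_d <- 0L
  }

  lambda_a <- vc$var_e / vc$var_a
  n_eq <- k + n_a + n_d
  C <- matrix(0, n_eq, n_eq)
  rhs <- numeric(n_eq)
  y <- pheno$y

  iF <- seq_len(k)
  iU <- k + seq_len(n_a)
  C[iF, iF] <- crossprod(Fmat)
  # F'Z: per-animal sums of the fixed design rows
  agg <- rowsum(Fmat, group = ia)
  FtZ <- matrix(0, k, n_a)
  FtZ[, as.integer(rownames(agg))] <- t(agg)
  C[iF, iU] <- FtZ
  C[iU, iF] <- t(FtZ)
  C[iU, iU] <- lambda_a * K_inv
  zz <- tabulate(ia, n_a)
  diag(C)[iU] <- diag(C)[iU] + zz
  rhs[iF] <- crossprod(Fmat, y)
  ragg <- rowsum(y, group = ia)
  rhs[iU][as.integer(rownames(ragg))] <- ragg

  if (use_pe) {
    iW <- k + n_a + seq_len(n_d)
    lambda_c <- vc$var_e / vc$var_c
    aggW <- rowsum(Fmat, group = idd)
    FtW <- matrix(0, k, n_d)
    FtW[, as.integer(rownames(aggW))] <- t(aggW)
    C[iF, iW] <- FtW
    C[iW, iF] <- t(FtW)
    ZtW <- unclass(table(factor(ia, levels = seq_len(n_a)),
                         factor(idd, levels = seq_len(n_d))))
    C[iU, iW] <- ZtW
    C[iW, iU] <- t(ZtW)
    diag(C)[iW] <- tabulate(idd, n_d) + lambda_c
    wagg <- rowsum(y, group = idd)
    rhs[iW][as.integer(rownames(wagg))] <- wagg
  }

  sol <- solve(C, rhs)
  rel_res <- max(abs(C %*% sol - rhs)) / max(1, max(abs(rhs)))

  fixed <- sol[iF]
  names(fixed) <- colnames(Fmat)
  u <- sol[iU]
  names(u) <- animals
  j_coef <- NULL
  gebv <- u
  if (k_j > 0) {
    j_coef <- rep(NA_real_, k_j)
    names(j_coef) <- colnames(J)
    est <- intersect(colnames(J), colnames(Fmat))
    j_coef[est] <- fixed[est]
    contrib <- ifelse(is.na(j_coef), 0, j_coef)
    gebv <- u + drop(J %*% contrib)
    fixed <- fixed[setdiff(colnames(Fmat), colnames(J))]
  }
  pe <- NULL
  if (use_pe) {
    pe <- sol[k + n_a + seq_len(n_d)]
    names(pe) <- dams
  }
  structure(list(fixed = fixed, j_coef = j_coef, j_estimable = j_estimable,
                 u = u, pe = pe, gebv = gebv, residual = rel_res,
                 n_equations = n_eq),
            class = "jf_solutions")
}

#' @export
print.jf_solutions <- function(x, ...) {
  cat("Mixed-model solutions:", length(x$u), "breeding values,",
      length(x$fixed), "fixed effects")
  if (!is.null(x$j_coef)) {
    cat(";", sum(x$j_estimable), "of", length(x$j_coef),
        "J coefficients estimable")
  }
  cat("\nrelative residual:", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Single-step SNPBLUP with explicit SNP effects
#'
#' Alternative parameterization of the single-step model in which the
#' additive genetic effect of each genotyped animal is decomposed as
#' `u_g = Z_g g + a_g` (SNP effects plus a residual polygenic effect) and
#' the SNP effects `g` are solved for explicitly. The joint prior
#' covariance of `[u; g]` is assembled from the single-step blocks, and
#' the same Henderson machinery as [solve_mme()] is applied, so the two
#' routes are mathematically equivalent; the reconstructed breeding
#' values, fixed effects, and GEBV agree with the `H`-matrix solve to
#' solver precision. Intended for desk-scale models (its system grows
#' with the number of SNPs).
#'
#' @inheritParams solve_mme
#' @param part a [rel_partition()] over all animals.
#' @param M dosage matrix of the genotyped animals (rownames = labels,
#'   entries 0/1/2).
#' @param w residual polygenic proportion of the additive variance; with
#'   `w = 1` the model degenerates to pedigree BLUP and all SNP effects
#'   are zero.
#' @return as [solve_mme()], with an extra element `snp` (estimated SNP
#'   effects) and `poly` (residual polygenic effects of genotyped
#'   animals, `u_g - Z_g g`).
#' @export
solve_snp_level <- function(pheno, part, M, w, varcomp, J = NULL) {
  stopifnot(inherits(part, "rel_partition"), w >= 0, w <= 1)
  g_lab <- part$genotyped
  M <- as.matrix(M)
  if (is.null(rownames(M)) || !setequal(rownames(M), g_lab)) {
    stop("rownames of M must be exactly the genotyped animals")
  }
  M <- M[g_lab, , drop = FALSE]
  cg <- center_genotypes(M)
  m <- ncol(M)
  snp_names <- if (!is.null(colnames(M))) colnames(M) else
    paste0("snp", seq_len(m))

  if (w >= 1) {
    # SNP effects have zero prior variance: pedigree BLUP with g = 0
    A <- rbind(cbind(part$A_nn, part$A_ng),
               cbind(t(part$A_ng), part$A_gg))
    A_inv <- chol2inv(chol(A))
    dimnames(A_inv) <- list(part$order, part$order)
    res <- solve_mme(pheno, A_inv, varcomp, J = J)
    res$snp <- stats::setNames(rep(0, m), snp_names)
    res$poly <- res$u[g_lab]
    return(res)
  }

  b <- build_B(cg$p, w)
  G <- build_G(cg$Z, b, w, part$A_gg)
  H <- assemble_H(part, G, route = "blocks")
  n_all <- nrow(H)
  # cross-covariances with the SNP effects
  Cug_g <- cg$Z * b                                   # g x m
  P <- solve_agg(part, t(part$A_ng))                  # g x n
  Cug_n <- t(P) %*% Cug_g                             # n x m
  Sigma <- matrix(0, n_all + m, n_all + m)
  Sigma[seq_len(n_all), seq_len(n_all)] <- H
  Sigma[seq_len(n_all), n_all + seq_len(m)] <- rbind(Cug_n, Cug_g)
  Sigma[n_all + seq_len(m), seq_len(n_all)] <-
    t(Sigma[seq_len(n_all), n_all + seq_len(m)])
  diag(Sigma)[n_all + seq_len(m)] <- b
  labels <- c(part$order, paste0(".snp.", snp_names))
  dimnames(Sigma) <- list(labels, labels)
  Sigma_inv <- solve(Sigma)
  Sigma_inv <- (Sigma_inv + t(Sigma_inv)) / 2

  J_ext <- NULL
  if (!is.null(J)) {
    J <- as.matrix(J)
    J_ext <- matrix(0, length(labels), ncol(J),
                    dimnames = list(labels, colnames(J)))
    J_ext[rownames(J), ] <- J
  }
  res <- solve_mme(pheno, Sigma_inv, varcomp, J = J_ext)
  v <- res$u
  u <- v[part$order]
  snp <- v[n_all + seq_len(m)]
  names(snp) <- snp_names
  res$u <- u
  res$snp <- snp
  res$poly <- u[g_lab] - drop(cg$Z %*% snp)
  res$gebv <- res$gebv[part$order]
  res
}
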