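#' Remove phenotype outliers within recording groups
#'
#' Drops records deviating strictly more than `threshold` standard
#' deviations from the mean of their recording group (e.g. day of
#' recording), in a single pass. Groups of size 1 are kept unfiltered
#' with a warning.
#'
#' @param pheno data.frame of phenotype records.
#' @param value column name holding the trait value.
#' @param group column name holding the recording group.
#' @param threshold SD multiplier (default 3.5); records at exactly the
#'   boundary are kept.
#' @return the filtered data.frame.
#' @export
outlier_filter <- function(pheno, value = "y", group = "group",
                           threshold = 3.5) {
  y <- pheno[[value]]
  gl <- as.character(pheno[[group]])
  keep <- rep(TRUE, nrow(pheno))
  singles <- FALSE
  for (g in unique(gl)) {
    idx <- which(gl == g)
    if (length(idx) < 2) {
      singles <- TRUE
      next
    }
    s <- stats::sd(y[idx])
    if (s == 0) next
    keep[idx] <- abs(y[idx] - mean(y[idx])) <= threshold * s
  }
  if (singles) warning("groups of size 1 kept unfiltered")
  pheno[keep, , drop = FALSE]
}

#' SNP quality control
#'
#' Retains SNPs passing (i) a minor-allele-frequency filter, (ii) a
#' Mendelian-consistency filter based on opposing homozygotes across
#' genotyped parent-offspring pairs resolved from the pedigree, and
#' (iii) a call-rate filter, applied only when missing values are present.
#'
#' @param M dosage matrix (animals x SNPs, rownames = labels; `NA` =
#'   missing call).
#' @param ped a [pedigree()] object used to resolve parent-offspring pairs
#'   among the genotyped animals.
#' @param maf_min minimum minor allele frequency (default 0.005; SNPs
#'   strictly below are removed).
#' @param mendel_max maximum tolerated rate of opposing homozygotes per
#'   SNP across parent-offspring pairs (default 0.01; strictly above is
#'   removed). Skipped with a warning when no genotyped pairs exist.
#' @param call_rate minimum per-SNP call rate (default 0.95), only
#'   enforced if `M` contains missing values.
#' @return character vector (or integer indices when `M` has no column
#'   names) of retained SNPs.
#' @export
snp_qc <- function(M, ped, maf_min = 0.005, mendel_max = 0.01,
                   call_rate = 0.95) {
  M <- as.matrix(M)
  snps <- if (!is.null(colnames(M))) colnames(M) else seq_len(ncol(M))
  keep <- rep(TRUE, ncol(M))

  if (anyNA(M)) {
    cr <- colMeans(!is.na(M))
    keep <- keep & cr >= call_rate
  }
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- keep & maf >= maf_min

  # parent-offspring pairs with both members genotyped
  ids <- rownames(M)
  pairs_o <- integer(0)
  pairs_p <- integer(0)
  for (i in seq_len(ped$n)) {
    if (!(ped$id[i] %in% ids)) next
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (par > 0L && ped$id[par] %in% ids) {
        pairs_o <- c(pairs_o, match(ped$id[i], ids))
        pairs_p <- c(pairs_p, match(ped$id[par], ids))
      }
    }
  }
  if (length(pairs_o) == 0) {
    warning("no genotyped parent-offspring pairs; Mendelian filter skipped")
  } else {
    O <- M[pairs_o, , drop = FALSE]
    P <- M[pairs_p, , drop = FALSE]
    opp <- (O == 0 & P == 2) | (O == 2 & P == 0)
    rate <- colMeans(opp, na.rm = TRUE)
    rate[is.nan(rate)] <- 0
    keep <- keep & rate <= mendel_max
  }
  snps[keep]
}

#' Cross-validation folds over sires
#'
#' Randomly partitions sires into `k` groups whose sizes differ by at most
#' one (161 sires with `k = 5` gives four groups of 32 and one of 33).
#' Each fold's sires' offspring form a validation set; the remainder form
#' the reference population.
#'
#' @param sires vector of sire labels.
#' @param k number of folds (default 5).
#' @param seed integer seed for the random partition.
#' @return integer vector of fold assignments (1..k), named by sire.
#' @export
make_folds <- function(sires, k = 5, seed = 1) {
  sires <- as.character(sires)
  n <- length(sires)
  if (k > n) stop("more folds than sires")
  set.seed(seed)
  shuffled <- sample(sires)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  stats::setNames(fold[match(sires, shuffled)], sires)
}

#' Select the genotyped subset of a reference population
#'
#' Implements the genotyping-scenario grid: a fraction `rate` of the
#' reference animals keeps its genotype, chosen uniformly at random
#' (`RND`) or as the top phenotypic performers for the trait (`TOP`, ties
#' broken by a seeded shuffle). Selection is meant to be applied within a
#' cross-validation fold's reference population; genotypes of unselected
#' animals are discarded by the caller.
#'
#' @param animals labels of the reference animals.
#' @param rate genotyping rate; one of 1, 0.75, 0.5, 0.25.
#' @param scheme `"RND"` or `"TOP"`.
#' @param phenotype numeric vector aligned with `animals` (required for
#'   `TOP`).
#' @param seed integer seed.
#' @return character vector of selected (genotyped) animals.
#' @export
apply_genotyping_scheme <- function(animals, rate, scheme = c("RND", "TOP"),
                                    phenotype = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (!rate %in% c(1, 0.75, 0.5, 0.25)) {
    stop("genotyping rate must be one of 1, 0.75, 0.5, 0.25")
  }
  animals <- as.character(animals)
  n_sel <- ceiling(rate * length(animals))
  set.seed(seed)
  if (scheme == "RND") {
    return(sample(animals, n_sel))
  }
  if (is.null(phenotype) || length(phenotype) != length(animals)) {
    stop("TOP selection needs one phenotype per reference animal")
  }
  ord <- order(phenotype, sample(length(animals)), decreasing = TRUE)
  animals[ord[seq_len(n_sel)]]
}

#' Reliability of a sire progeny mean (Cameron)
#'
#' `(n h^2 / 4) / (1 + (n - 1) h^2 / 4)`: the precision weight of a
#' progeny-mean record from `n` half-sib offspring under heritability
#' `h2`. Strictly increasing in both arguments, tending to 1 as
#' `n` grows.
#'
#' @param n number of offspring with records (>= 1).
#' @param h2 heritability in (0, 1).
#' @return reliability in (0, 1).
#' @export
cameron_reliability <- function(n, h2) {
  stopifnot(all(n >= 1), all(h2 > 0), all(h2 < 1))
  (0.25 * n * h2) / (1 + 0.25 * (n - 1) * h2)
}

#' Sire progeny means corrected for environmental effects
#'
#' Fits a sire model (combined environmental factor as fixed cell means
#' plus an i.i.d. random sire effect with the variance ratio implied by
#' `h2/4` of the phenotypic variance) to the full data, corrects each
#' record by its estimated fixed effect, and averages corrected records
#' per sire. Reliabilities come from [cameron_reliability()] with each
#' sire's offspring count.
#'
#' @param pheno data.frame with columns `sire`, `y`, `fixed`.
#' @param h2 heritability used for the sire variance ratio and the
#'   reliabilities.
#' @param min_offspring sires with fewer offspring are excluded (with a
#'   warning); default 2.
#' @return data.frame with columns `sire`, `n_offspring`, `progeny_mean`,
#'   `reliability`.
#' @export
sire_progeny_means <- function(pheno, h2, min_offspring = 2) {
  stopifnot(h2 > 0, h2 < 1)
  sire <- as.character(pheno$sire)
  f <- droplevels(factor(pheno$fixed))
  y <- pheno$y
  sires <- sort(unique(sire))
  ns <- length(sires)
  X <- matrix(0, length(y), nlevels(f))
  X[cbind(seq_along(y), as.integer(f))] <- 1
  isr <- match(sire, sires)
  var_p <- stats::var(y)
  lambda <- (1 - h2 / 4) / (h2 / 4)      # residual-to-sire variance ratio
  k <- ncol(X)
  C <- matrix(0, k + ns, k + ns)
  C[seq_len(k), seq_len(k)] <- crossprod(X)
  agg <- rowsum(X, group = isr)
  XtS <- matrix(0, k, ns)
  XtS[, as.integer(rownames(agg))] <- t(agg)
  C[seq_len(k), k + seq_len(ns)] <- XtS
  C[k + seq_len(ns), seq_len(k)] <- t(XtS)
  diag(C)[k + seq_len(ns)] <- tabulate(isr, ns) + lambda
  rhs <- c(crossprod(X, y), rowsum(y, group = isr)[, 1])
  # cell-means X with random sire is full rank; guard all the same
  sol <- tryCatch(solve(C, rhs), error = function(e) qr.solve(C, rhs))
  bhat <- sol[seq_len(k)]
  corrected <- y - drop(X %*% bhat)
  pm <- rowsum(corrected, group = isr)[, 1] / tabulate(isr, ns)
  n_off <- tabulate(isr, ns)
  out <- data.frame(sire = sires, n_offspring = n_off,
                    progeny_mean = pm,
                    reliability = cameron_reliability(pmax(n_off, 1), h2),
                    stringsAsFactors = FALSE)
  small <- out$n_offspring < min_offspring
  if (any(small)) {
    warning(sum(small), " sire(s) with fewer than ", min_offspring,
            " offspring excluded")
    out <- out[!small, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Weighted Pearson correlation
#'
#' Weighted correlation based on weighted means and weighted central
#' moments; with equal weights it reduces exactly to the ordinary Pearson
#' correlation. Used with progeny-mean reliabilities as weights to
#' estimate the accuracy of sire GEBV.
#'
#' @param x,y numeric vectors.
#' @param w non-negative weights.
#' @return correlation, or `NA` when a weighted variance vanishes.
#' @export
weighted_cor <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w >= 0))
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Dispersion of sire GEBV: doubled weighted regression slope
#'
#' Weighted least-squares regression of sire progeny means on sire GEBV,
#' multiplied by 2 so that the expectation for unbiased breeding values is
#' 1 on the individual scale (a progeny mean reflects half the sire's
#' breeding value). Values below 1 indicate inflated GEBV variance.
#'
#' @param gebv sire GEBV.
#' @param progeny_mean corrected progeny means, aligned with `gebv`.
#' @param w weights (reliabilities).
#' @return the doubled slope, or `NA` when the weighted variance of
#'   `gebv` vanishes.
#' @export
dispersion_slope <- function(gebv, progeny_mean, w = rep(1, length(gebv))) {
  stopifnot(length(gebv) == length(progeny_mean),
            length(w) == length(gebv), all(w >= 0))
  w <- w / sum(w)
  mx <- sum(w * gebv)
  my <- sum(w * progeny_mean)
  vx <- sum(w * (gebv - mx)^2)
  if (vx <= 0) return(NA_real_)
  2 * sum(w * (gebv - mx) * (progeny_mean - my)) / vx
}

#' Round half away from zero
#'
#' Reporting convention for result tables (two decimals by default).
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
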