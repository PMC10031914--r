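#' J-factor covariates by the direct dense formula
#'
#' Computes the covariate(s) that model the mean performance of genotyped
#' animals when SNP genotypes are centred at observed allele frequencies.
#' Genotyped animals receive `-Q` (for the single-covariate case, exactly
#' `-1`); ungenotyped animals receive the pedigree regression
#' `-A_ng A_gg^{-1} Q`. Ungenotyped animals with no genotyped relatives end
#' up with all-zero rows. The single covariate lies in `[-2, 0]`; with
#' several breeds the per-animal row sums reproduce the single covariate
#' (and hence its range), while individual breed columns respect the bound
#' under the crossbred structures the fractions describe but can overshoot
#' it slightly on arbitrary pedigrees.
#'
#' @param part a [rel_partition()] over the full pedigree.
#' @param Q breed-fraction matrix for the genotyped animals (one row per
#'   genotyped animal, rows summing to 1, rownames = animal labels), or
#'   `NULL` for the single J-factor (a column of ones).
#' @return numeric matrix, one row per pedigree animal (pedigree order),
#'   one column per J-factor, with attributes `method_tag` (`"ONE"` or the
#'   `source_tag` of `Q`) and `genotyped`.
#' @seealso [jfactor_efficient()] for the ancestor-restricted equivalent.
#' @export
jfactor_direct <- function(part, Q = NULL) {
  stopifnot(inherits(part, "rel_partition"))
  g <- part$genotyped
  Q <- check_Q(Q, g)
  Jg <- -Q
  Jn <- -part$A_ng %*% solve_agg(part, Q)
  rownames(Jg) <- g
  rownames(Jn) <- part$nongenotyped
  J <- rbind(Jn, Jg)[part$ped_id, , drop = FALSE]
  structure(J,
            method_tag = attr(Q, "source_tag"),
            genotyped = g)
}

# validate or default the genotyped breed-fraction matrix
check_Q <- function(Q, genotyped, tol = 1e-8) {
  if (is.null(Q)) {
    Q <- matrix(1, length(genotyped), 1,
                dimnames = list(genotyped, "J"))
    attr(Q, "source_tag") <- "ONE"
    return(Q)
  }
  Q <- as.matrix(Q)
  if (is.null(rownames(Q))) {
    stop("Q must carry animal labels as rownames")
  }
  if (!setequal(rownames(Q), genotyped)) {
    stop("rownames of Q must be exactly the genotyped animals")
  }
  Q <- Q[genotyped, , drop = FALSE]
  rs <- rowSums(Q)
  if (max(abs(rs - 1)) > tol) {
    worst <- which.max(abs(rs - 1))
    stop("rows of Q must sum to 1; worst offender ", rownames(Q)[worst],
         " with row sum ", format(rs[worst]))
  }
  if (is.null(attr(Q, "source_tag"))) attr(Q, "source_tag") <- "MULTI"
  Q
}

#' J-factor covariates by ancestor-restricted propagation
#'
#' Equivalent to [jfactor_direct()] but restricts the dense solve to the
#' genotyped animals and their pedigree ancestors; every remaining animal
#' (no genotyped descendant) receives the average of its parents' covariate
#' rows, processed from oldest to youngest, with unknown parents
#' contributing zero rows. For such animals the tabular recursion makes the
#' parent average exact, so the two routes agree to solver precision.
#'
#' @param ped a [pedigree()] object.
#' @param genotyped labels of genotyped animals.
#' @inheritParams jfactor_direct
#' @return as [jfactor_direct()], rows in pedigree order of `ped`.
#' @export
jfactor_efficient <- function(ped, genotyped, Q = NULL) {
  stopifnot(inherits(ped, "jf_ped"))
  genotyped <- as.character(genotyped)
  gset <- ped$id %in% genotyped
  if (!any(gset)) stop("genotyped set is empty; J is undefined")

  # closure: genotyped animals plus all their ancestors
  keep <- gset
  for (i in rev(seq_len(ped$n))) {
    if (keep[i]) {
      if (ped$sire[i] > 0L) keep[ped$sire[i]] <- TRUE
      if (ped$dam[i] > 0L) keep[ped$dam[i]] <- TRUE
    }
  }
  sub_idx <- which(keep)
  # sub-pedigree is closed under parents, so relationships are unchanged
  remap <- integer(ped$n)
  remap[sub_idx] <- seq_along(sub_idx)
  sub <- list(id = ped$id[sub_idx],
              sire = ifelse(ped$sire[sub_idx] > 0L,
                            remap[pmax(ped$sire[sub_idx], 1L)], 0L),
              dam = ifelse(ped$dam[sub_idx] > 0L,
                           remap[pmax(ped$dam[sub_idx], 1L)], 0L),
              n = length(sub_idx))
  class(sub) <- "jf_ped"
  part <- rel_partition(sub, genotyped)
  Jsub <- jfactor_direct(part, Q)

  k <- ncol(Jsub)
  J <- matrix(0, ped$n, k, dimnames = list(ped$id, colnames(Jsub)))
  J[sub$id, ] <- Jsub
  # parent-average propagation for non-ancestors, oldest to youngest;
  # an unknown parent contributes a zero row (the average still halves)
  for (i in which(!keep)) {
    row <- numeric(k)
    if (ped$sire[i] > 0L) row <- row + J[ped$sire[i], ]
    if (ped$dam[i] > 0L) row <- row + J[ped$dam[i], ]
    J[i, ] <- row / 2
  }
  structure(J,
            method_tag = attr(Jsub, "method_tag"),
            genotyped = attr(Jsub, "genotyped"))
}

#' Row-sum identity between multi- and single-J covariates
#'
#' Because breed-fraction rows sum to 1, the per-animal row sums of a
#' multi-breed J covariate matrix must reproduce the single J-factor vector
#' of the same pedigree and genotyped set. This check makes that identity
#' an explicit diagnostic.
#'
#' @param J_multi animals-by-b covariate matrix (EXP or OBS).
#' @param J_one animals-by-1 covariate matrix (or vector) from the single
#'   J-factor.
#' @param tol tolerance on the per-animal discrepancy.
#' @return list with `ok` (logical), `max_diff`, and `worst` (the animal
#'   label with the largest discrepancy).
#' @export
jfactor_rowsum_check <- function(J_multi, J_one, tol = 1e-8) {
  J_multi <- as.matrix(J_multi)
  J_one <- as.matrix(J_one)
  if (nrow(J_multi) != nrow(J_one)) {
    stop("J_multi and J_one cover different numbers of animals")
  }
  d <- abs(rowSums(J_multi) - J_one[, 1])
  worst <- which.max(d)
  list(ok = max(d) <= tol,
       max_diff = max(d),
       worst = if (!is.null(rownames(J_multi))) rownames(J_multi)[worst]
               else worst)
}

#' Write J-factor covariates to a TSV file
#'
#' @param J covariate matrix from [jfactor_direct()] or
#'   [jfactor_efficient()].
#' @param path output file.
#' @export
write_jfactor <- function(J, path) {
  df <- data.frame(animal = rownames(J), as.data.frame(unclass(J)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
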