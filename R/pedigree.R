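#' Build and validate a pedigree
#'
#' Validates raw pedigree rows (animal, sire, dam; unknown parents coded 0 or
#' `NA`) and returns a topologically sorted pedigree in which every parent
#' precedes its offspring. Labels may arrive in any order; they are preserved
#' and mapped to consecutive internal indices.
#'
#' @param animal vector of animal labels (integer or character), one per row.
#' @param sire,dam parent labels; `0`, `"0"` or `NA` mark an unknown parent.
#'
#' @return An object of class `jf_ped`: a list with elements
#'   `id` (character labels in sorted order), `sire` and `dam`
#'   (integer indices into `id`, `0` = unknown), and `n`.
#'
#' @details Cycles (an animal among its own ancestors) and parents that never
#'   appear as an animal record are errors. Sorting is Kahn's algorithm on the
#'   parent-to-offspring edges, so `order` is a valid processing order for all
#'   recursive pedigree algebra in this package.
#'
#' @examples
#' ped <- pedigree(c("o", "s", "d"), c("s", 0, 0), c("d", 0, 0))
#' ped$id   # founders first
#' @export
pedigree <- function(animal, sire, dam) {
  id <- as.character(animal)
  s <- as.character(sire)
  d <- as.character(dam)
  s[is.na(s)] <- "0"
  d[is.na(d)] <- "0"
  if (anyDuplicated(id)) {
    stop("duplicated animal labels: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(id == "0")) stop("'0' is reserved for unknown parents")
  n <- length(id)
  pos <- seq_len(n)
  names(pos) <- id
  miss <- setdiff(c(s[s != "0"], d[d != "0"]), id)
  if (length(miss) > 0) {
    stop("parent labels never defined as animals: ",
         paste(sort(unique(miss)), collapse = ", "))
  }
  si <- ifelse(s == "0", 0L, pos[s])
  di <- ifelse(d == "0", 0L, pos[d])

  # Kahn toposort over parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    on_cycle <- id[setdiff(seq_len(n), ord)]
    stop("pedigree contains a cycle involving animal: ", on_cycle[[1]])
  }
  newpos <- integer(n)
  newpos[ord] <- seq_len(n)
  out <- list(id = id[ord],
              sire = ifelse(si[ord] > 0L, newpos[pmax(si[ord], 1L)], 0L),
              dam = ifelse(di[ord] > 0L, newpos[pmax(di[ord], 1L)], 0L),
              n = n)
  class(out) <- "jf_ped"
  out
}

#' @export
print.jf_ped <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat("Pedigree with", x$n, "animals (", nf, "founders ), sorted\n")
  invisible(x)
}

#' @export
as.data.frame.jf_ped <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(x$sire > 0L, x$id[pmax(x$sire, 1L)], "0"),
             dam = ifelse(x$dam > 0L, x$id[pmax(x$dam, 1L)], "0"),
             stringsAsFactors = FALSE)
}

#' Numerator relationship matrix
#'
#' Computes the full pedigree-based (numerator) relationship matrix by the
#' recursive tabular method, accounting for inbreeding:
#' `a(i,i) = 1 + F_i` with `F_i = a(sire_i, dam_i)/2`, and
#' `a(i,j) = (a(sire_i, j) + a(dam_i, j))/2` for older `j`. Unknown parents
#' contribute nothing (a single, non-inbred, unrelated base population).
#'
#' @param ped a [pedigree()] object.
#' @return dense symmetric matrix with animal labels as dimnames.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "jf_ped"))
  n <- ped$n
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- ped$sire
  di <- ped$dam
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[s, j]
      if (d > 0L) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector `F` per animal (diagonal of A minus 1).
#' @export
inbreeding <- function(ped) {
  diag(a_matrix(ped)) - 1
}

#' Partition the relationship matrix by genotyped status
#'
#' Splits the numerator relationship matrix into the blocks
#' `A_nn`, `A_ng`, `A_gg` between non-genotyped (n) and genotyped (g)
#' animals, the partition all single-step and J-factor algebra rests on.
#'
#' @param ped a [pedigree()] object.
#' @param genotyped labels of genotyped animals (non-empty subset of `ped$id`).
#' @param A optionally, a precomputed `a_matrix(ped)` to slice.
#' @return object of class `rel_partition`: list with `A_nn`, `A_ng`, `A_gg`,
#'   `genotyped`, `nongenotyped` (labels in pedigree order), and `order`
#'   (labels, non-genotyped first) describing the block arrangement.
#' @export
rel_partition <- function(ped, genotyped, A = NULL) {
  stopifnot(inherits(ped, "jf_ped"))
  genotyped <- as.character(genotyped)
  if (length(genotyped) == 0) {
    stop("genotyped set is empty; the partition (and J) is undefined")
  }
  bad <- setdiff(genotyped, ped$id)
  if (length(bad) > 0) {
    stop("genotyped labels not in pedigree: ", paste(bad, collapse = ", "))
  }
  if (is.null(A)) A <- a_matrix(ped)
  g <- ped$id[ped$id %in% genotyped]       # pedigree order
  ng <- setdiff(ped$id, g)
  out <- list(A_nn = A[ng, ng, drop = FALSE],
              A_ng = A[ng, g, drop = FALSE],
              A_gg = A[g, g, drop = FALSE],
              genotyped = g,
              nongenotyped = ng,
              order = c(ng, g),
              ped_id = ped$id)
  class(out) <- "rel_partition"
  out
}

#' @export
print.rel_partition <- function(x, ...) {
  cat("Relationship partition:", length(x$nongenotyped), "non-genotyped,",
      length(x$genotyped), "genotyped animals\n")
  invisible(x)
}

#' Solve linear systems against the genotyped block
#'
#' Returns `X` with `A_gg X = M` via a Cholesky factorization, the
#' workhorse behind the J-factor regression of ungenotyped on genotyped
#' animals. Fails with a diagnostic when `A_gg` is numerically singular
#' (typically a duplicated individual in the genotyped set).
#'
#' @param part a [rel_partition()].
#' @param M numeric matrix (or vector) with rows matching the genotyped block.
#' @return matrix `A_gg^{-1} M`.
#' @export
solve_agg <- function(part, M) {
  stopifnot(inherits(part, "rel_partition"))
  M <- as.matrix(M)
  stopifnot(nrow(M) == nrow(part$A_gg))
  R <- tryCatch(chol(part$A_gg), error = function(e) NULL)
  if (is.null(R)) {
    # locate a nearly dependent pair to report
    g <- part$genotyped
    hint <- ""
    if (length(g) > 1) {
      Agg <- part$A_gg
      sc <- sqrt(diag(Agg))
      C <- Agg / outer(sc, sc)
      diag(C) <- 0
      idx <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
      hint <- paste0("; most collinear pair: ", g[idx[1]], " and ", g[idx[2]])
    }
    stop("A_gg is numerically singular (duplicated individuals?)", hint)
  }
  backsolve(R, backsolve(R, M, transpose = TRUE))
}
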