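#' Pedigree-expected breed fractions
#'
#' Builds the breed-fraction matrix Q from pedigree expectation: animals
#' with a known purebred origin receive a unit row (1 in the column of
#' their breed), and every other animal receives the average of its
#' parents' rows, processed in pedigree order. In a three-way cross
#' A x (B x C) this yields (0, 0.5, 0.5) for F1 dams and
#' (0.5, 0.25, 0.25) for the crossbreds, with the sire breed first.
#'
#' @param ped a [pedigree()] object.
#' @param founder_breed named character vector mapping animal labels to
#'   breed labels; must cover every animal whose parents are not both known
#'   (in particular all founders).
#' @param breeds optional character vector fixing the column order
#'   (conventionally the sire breed first); defaults to the order of first
#'   appearance in `founder_breed`.
#' @return matrix animals x breeds with rows summing to 1,
#'   attribute `source_tag = "EXP"`.
#' @export
expected_breed_fractions <- function(ped, founder_breed, breeds = NULL) {
  stopifnot(inherits(ped, "jf_ped"))
  founder_breed <- founder_breed[!is.na(founder_breed)]
  if (is.null(breeds)) breeds <- unique(unname(founder_breed))
  if (!all(founder_breed %in% breeds)) {
    stop("founder breeds outside the declared breed set: ",
         paste(setdiff(founder_breed, breeds), collapse = ", "))
  }
  bad <- setdiff(names(founder_breed), ped$id)
  if (length(bad) > 0) {
    stop("breed assignments for unknown animals: ", paste(bad, collapse = ", "))
  }
  b <- length(breeds)
  Q <- matrix(0, ped$n, b, dimnames = list(ped$id, breeds))
  assigned <- ped$id %in% names(founder_breed)
  Q[names(founder_breed), ] <-
    outer(unname(founder_breed), breeds, "==") + 0
  for (i in seq_len(ped$n)) {
    if (assigned[i]) next
    if (ped$sire[i] == 0L || ped$dam[i] == 0L) {
      stop("animal ", ped$id[i], " has an unknown parent and no breed ",
           "assignment; assign its breed in 'founder_breed'")
    }
    Q[i, ] <- (Q[ped$sire[i], ] + Q[ped$dam[i], ]) / 2
  }
  structure(Q, source_tag = "EXP")
}

#' Scale observed breed fractions of three-way crossbreds
#'
#' Standardizes raw genome-based (breed-of-origin) fractions of
#' A x (B x C) crossbreds so that they carry the structure the cross
#' guarantees, in three steps:
#' \enumerate{
#'   \item the sire-breed column is fixed at 0.5 (the exact paternal
#'     contribution to a three-way crossbred);
#'   \item each dam-breed column is multiplied by the ratio of 0.25 to its
#'     mean over all crossbreds, so both dam breeds average to their
#'     expected value of 0.25;
#'   \item per animal, the two dam entries are rescaled so that they sum
#'     to 0.5.
#' }
#' Step 3 perturbs the column means slightly; they are not re-corrected.
#' The transformation is idempotent and leaves exact expected fractions
#' (0.5, 0.25, 0.25) unchanged.
#'
#' @param raw crossbreds x 3 matrix of raw fractions, columns ordered
#'   (sire breed, dam breed B, dam breed C); rows should sum to
#'   approximately 1.
#' @return matrix of the same shape with rows summing to 1 exactly,
#'   attribute `source_tag = "OBS"`.
#' @export
scale_observed_fractions <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 3) {
    stop("expected 3 columns (sire breed, dam breed B, dam breed C)")
  }
  if (any(raw < 0)) stop("negative raw breed fractions")
  rs <- rowSums(raw)
  if (max(abs(rs - 1)) > 0.2) {
    warning("raw fraction rows deviate from sum 1 by up to ",
            format(max(abs(rs - 1)), digits = 3))
  }
  out <- raw
  out[, 1] <- 0.5
  for (j in 2:3) {
    m <- mean(raw[, j])
    if (m <= 0) stop("dam-breed column ", j - 1, " has zero mean")
    out[, j] <- raw[, j] * (0.25 / m)
  }
  dam_sum <- out[, 2] + out[, 3]
  if (any(dam_sum <= 0)) {
    stop("some animals have zero combined dam-breed contribution")
  }
  out[, 2] <- out[, 2] * 0.5 / dam_sum
  out[, 3] <- out[, 3] * 0.5 / dam_sum
  structure(out, source_tag = "OBS")
}

#' Read / write breed-fraction tables
#'
#' TSV layout: `animal` column plus one fraction column per breed.
#' @param Q fraction matrix with animal rownames.
#' @param path file path.
#' @export
write_breed_fractions <- function(Q, path) {
  df <- data.frame(animal = rownames(Q), as.data.frame(unclass(Q)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breed_fractions
#' @export
read_breed_fractions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  Q <- as.matrix(df[, -1, drop = FALSE])
  rownames(Q) <- as.character(df[[1]])
  Q
}
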