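#' Read a pedigree CSV
#'
#' Expects a header and columns `animal,sire,dam`; unknown parents are
#' coded 0. Quoted or unquoted integer (or string) labels are accepted.
#'
#' @param path CSV file.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns animal,sire,dam")
  }
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree CSV
#' @param ped a [pedigree()] object.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Tab- or comma-separated matrix with animal labels in the first column
#' and one 0/1/2 dosage column per SNP.
#'
#' @param path file path.
#' @param sep field separator (guessed from the extension by default).
#' @return numeric matrix, animals x SNPs.
#' @export
read_dosages <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "numeric"
  rownames(M) <- as.character(df[[1]])
  M
}

#' Write a genotype dosage matrix as TSV
#' @param M dosage matrix with animal rownames.
#' @param path output file.
#' @export
write_dosages <- function(M, path) {
  df <- data.frame(animal = rownames(M), as.data.frame(M),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLINK .raw additive dosage file
#'
#' Whitespace-delimited dialect with the header
#' `FID IID PAT MAT SEX PHENOTYPE SNP1 SNP2 ...`; SNP columns hold 0/1/2
#' allele dosages (PLINK `--recode A`). `IID` becomes the animal label;
#' the pedigree and sex columns are ignored.
#'
#' @param path file path.
#' @return numeric dosage matrix, animals x SNPs.
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(df)[seq_len(6)])) {
    stop("not a PLINK .raw file: expected header FID IID PAT MAT SEX ",
         "PHENOTYPE ...")
  }
  M <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(M) <- "numeric"
  rownames(M) <- as.character(df$IID)
  M
}

#' Write mixed-model solutions
#'
#' `solutions.tsv` holds `animal, gebv, u_hat`; when J-factors were
#' fitted, `j_coefficients.tsv` holds the estimated genotype-mean
#' regression(s) next to it.
#'
#' @param sol a `jf_solutions` object from [solve_mme()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_solutions <- function(sol, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "solutions.tsv")
  utils::write.table(
    data.frame(animal = names(sol$u), gebv = unname(sol$gebv),
               u_hat = unname(sol$u)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(sol$j_coef)) {
    p2 <- file.path(dir, "j_coefficients.tsv")
    utils::write.table(
      data.frame(coef = names(sol$j_coef), estimate = unname(sol$j_coef),
                 estimable = unname(sol$j_estimable)),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
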