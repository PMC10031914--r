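# Fixture builders shared across the suite. All randomness is seeded by the
# caller so every test is reproducible.

# Random valid pedigree: founders first, later animals draw parents from
# earlier animals (possibly unknown). Returns the jf_ped plus the raw rows
# in shuffled order for exercising the sort.
rand_pedigree <- function(n, seed = 1, p_unknown = 0.15, n_founders = NULL,
                          joint_parents = FALSE) {
  set.seed(seed)
  if (is.null(n_founders)) n_founders <- max(2L, round(0.25 * n))
  sire <- dam <- character(n)
  id <- paste0("ind", seq_len(n))
  for (i in seq_len(n)) {
    if (i <= n_founders) {
      sire[i] <- dam[i] <- "0"
    } else if (joint_parents) {
      # parents are both known or both unknown (clean founder structure)
      if (stats::runif(1) < p_unknown) {
        sire[i] <- dam[i] <- "0"
      } else {
        pool <- id[seq_len(i - 1L)]
        sire[i] <- sample(pool, 1)
        dam[i] <- sample(pool, 1)
      }
    } else {
      pool <- id[seq_len(i - 1L)]
      sire[i] <- if (stats::runif(1) < p_unknown) "0" else sample(pool, 1)
      dam[i] <- if (stats::runif(1) < p_unknown) "0" else sample(pool, 1)
    }
  }
  shuffle <- sample(n)
  list(ped = pedigree(id, sire, dam),
       raw = data.frame(animal = id, sire = sire, dam = dam,
                        stringsAsFactors = FALSE)[shuffle, ])
}

# Monte-Carlo gene-dropping estimate of the relationship matrix: founders
# carry two unique alleles, offspring inherit one random allele per parent,
# and a(i,j) is estimated as twice the kinship (allele-sharing probability).
# Independent of the tabular method used by a_matrix(). Returns the estimate
# and its elementwise standard error.
gene_drop_kinship <- function(ped, nrep = 20000, seed = 1) {
  set.seed(seed)
  n <- ped$n
  al1 <- matrix(0L, nrep, n)
  al2 <- matrix(0L, nrep, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (s > 0L) {
      pick <- stats::runif(nrep) < 0.5
      al1[, i] <- ifelse(pick, al1[, s], al2[, s])
    } else {
      al1[, i] <- 2L * i - 1L
    }
    if (d > 0L) {
      pick <- stats::runif(nrep) < 0.5
      al2[, i] <- ifelse(pick, al1[, d], al2[, d])
    } else {
      al2[, i] <- 2L * i
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        v <- 1 + (al1[, i] == al2[, i])
      } else {
        v <- ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
                (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 2
      }
      est[i, j] <- est[j, i] <- mean(v)
      se[i, j] <- se[j, i] <- stats::sd(v) / sqrt(nrep)
    }
  }
  list(est = est, se = se)
}

# Three-breed family fixture: nb founders per breed (A sires first), an F1
# B x C dam tier, and crossbred offspring; small and fully labelled.
three_way_fixture <- function(n_sires = 3, n_b = 2, n_c = 2, n_dams = 4,
                              n_off = 2, seed = 1) {
  set.seed(seed)
  a <- paste0("A", seq_len(n_sires))
  b <- paste0("B", seq_len(n_b))
  c_ <- paste0("C", seq_len(n_c))
  d <- paste0("D", seq_len(n_dams))
  x <- paste0("X", seq_len(n_dams * n_off))
  d_sire <- sample(b, n_dams, replace = TRUE)
  d_dam <- sample(c_, n_dams, replace = TRUE)
  x_dam <- rep(d, each = n_off)
  x_sire <- sample(a, n_dams * n_off, replace = TRUE)
  ped <- pedigree(c(a, b, c_, d, x),
                  c(rep(0, n_sires + n_b + n_c), d_sire, x_sire),
                  c(rep(0, n_sires + n_b + n_c), d_dam, x_dam))
  founder_breed <- stats::setNames(
    c(rep("A", n_sires), rep("B", n_b), rep("C", n_c)), c(a, b, c_))
  list(ped = ped, founder_breed = founder_breed,
       sires = a, dams = d, crossbreds = x)
}

# Small simulated population for solver tests.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_snps = 200, n_sires = 10, n_a_gsires = 4,
                    n_a_gdams = 8, n_b_founders = 6, n_c_founders = 8,
                    n_dams = 30, offspring_per_mating = 4, seed = seed, ...)
  suppressWarnings(simulate_crossbred_population(cfg))
}
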