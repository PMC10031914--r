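#' Configuration of the synthetic three-way cross
#'
#' Defaults describe the experimental design the package targets: three
#' divergent purebred lines (A, B, C; mean pairwise F_ST 0.24), 161 breed-A
#' sires mated to F1 B x C dams, a single generation of three-way crossbred
#' offspring hatched across 5 batches housed in 20 pens with near-equal sex
#' ratios, and an additive + non-genetic maternal permanent environment +
#' residual variance structure (early body-weight magnitudes: 69.01, 43.73
#' and 151.07, heritability 0.26) with 5% of the additive variance kept as
#' residual polygenic. Population and marker counts default to a desk-scale
#' population of about two thousand crossbreds and two thousand independent
#' SNPs.
#'
#' @param n_snps number of SNPs.
#' @param n_sires number of purebred A sires (default 161).
#' @param n_a_gsires,n_a_gdams breed-A grandparents from which the sires
#'   descend; the resulting (half-)sib structure among sires is what ties
#'   validation sires to the reference data once their own offspring are
#'   held out.
#' @param n_b_founders,n_c_founders purebred B sires and C dams founding
#'   the F1 dam tier.
#' @param n_dams number of F1 (B x C) dams.
#' @param offspring_per_mating crossbred offspring per sire x dam mating.
#' @param target_fst divergence between the three purebred lines, in
#'   (0, 0.5).
#' @param n_batches,n_pens hatch batches and total pens (pens are split
#'   evenly across batches).
#' @param pen_fidelity probability that a crossbred is housed in its
#'   sire's primary pen for the batch (the rest scatter within the batch).
#' @param var_a,var_c,var_e additive, maternal permanent environmental and
#'   residual variances (trait units squared).
#' @param w_true proportion of additive variance simulated as residual
#'   polygenic rather than SNP-driven.
#' @param trait_mean overall trait mean.
#' @param fixed_sd SD of the combined batch-pen-sex level effects;
#'   `NULL` means half the phenotypic SD.
#' @param frac_noise_sd SD of the noise added to true breed-of-origin
#'   fractions to mimic imperfect breed-of-origin assignment.
#' @param seed integer seed; a given configuration reproduces its
#'   population exactly.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000,
                       n_sires = 161,
                       n_a_gsires = 25,
                       n_a_gdams = 80,
                       n_b_founders = 60,
                       n_c_founders = 120,
                       n_dams = 644,
                       offspring_per_mating = 3,
                       target_fst = 0.24,
                       n_batches = 5,
                       n_pens = 20,
                       pen_fidelity = 0.8,
                       var_a = 69.01,
                       var_c = 43.73,
                       var_e = 151.07,
                       w_true = 0.05,
                       trait_mean = 179,
                       fixed_sd = NULL,
                       frac_noise_sd = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_snps > 0, cfg$n_sires > 0, cfg$n_dams > 0,
            cfg$n_a_gsires > 0, cfg$n_a_gdams > 0,
            cfg$n_b_founders > 0, cfg$n_c_founders > 0,
            cfg$offspring_per_mating > 0,
            cfg$target_fst > 0, cfg$target_fst < 0.5,
            cfg$var_a > 0, cfg$var_c > 0, cfg$var_e > 0,
            cfg$w_true >= 0, cfg$w_true <= 1,
            cfg$n_pens %% cfg$n_batches == 0)
  if (is.null(cfg$fixed_sd)) {
    cfg$fixed_sd <- 0.5 * sqrt(cfg$var_a + cfg$var_c + cfg$var_e)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Breed-specific allele frequencies for divergent purebred lines
#'
#' Ancestral frequencies are drawn uniformly on (0.05, 0.95); each breed's
#' frequencies follow a Balding-Nichols distribution around the ancestral
#' value with divergence parameter `target_fst`, i.e.
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. The realized mean pairwise F_ST of the
#' generated frequencies matches the target up to Monte-Carlo error.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `p_anc` (length `n_snps`) and `p_breed`
#'   (3 x `n_snps` matrix, rows A, B, C).
#' @export
simulate_founder_breeds <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_snps
  p <- stats::runif(m, 0.05, 0.95)
  Fst <- config$target_fst
  shape_scale <- (1 - Fst) / Fst
  p_breed <- matrix(0, 3, m, dimnames = list(c("A", "B", "C"), NULL))
  for (k in 1:3) {
    p_breed[k, ] <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
  }
  # guard against numerically fixed alleles
  p_breed <- pmin(pmax(p_breed, 1e-4), 1 - 1e-4)
  list(p_anc = p, p_breed = p_breed)
}

#' Hudson-style pairwise F_ST between two frequency vectors
#'
#' Ratio-of-means estimator `mean((p1-p2)^2) / mean(p1(1-p2)+p2(1-p1))`,
#' used to monitor the realized divergence of the simulated lines.
#' @param p1,p2 allele-frequency vectors.
#' @export
pairwise_fst <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

#' Pedigree and housing of the three-way cross
#'
#' Builds the breed-A grandparent tier, the A sires descending from it,
#' the B and C founders, F1 B x C dams, and the crossbred generation:
#' each F1 dam is mated to one A sire (dams spread evenly over sires),
#' producing `offspring_per_mating` offspring. The grandparent tier makes
#' the sires (half-)sibs of one another, so a sire still has informative
#' relatives when its own offspring are held out for validation.
#' Crossbreds are hatched in batches; each sire has a primary pen per
#' batch and the majority of its offspring (probability `pen_fidelity`)
#' are housed there, with near-equal sex ratios. The combined
#' environmental factor is pen x sex (pens are nested in batches).
#'
#' @inheritParams simulate_founder_breeds
#' @return list with `ped` (a [pedigree()]), `meta` (data.frame with
#'   `animal`, `type` in SIRE_A/FOUNDER_B/FOUNDER_C/DAM_F1/CROSS, `sire`,
#'   `dam`, `batch`, `pen`, `sex`, `fixed`), and `founder_breed` (named
#'   vector for [expected_breed_fractions()]).
#' @export
build_cross_pedigree <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gs_id <- paste0("GS", seq_len(config$n_a_gsires))
  gd_id <- paste0("GD", seq_len(config$n_a_gdams))
  a_id <- paste0("A", seq_len(config$n_sires))
  a_sire <- sample(gs_id, config$n_sires, replace = TRUE)
  a_dam <- sample(gd_id, config$n_sires, replace = TRUE)
  b_id <- paste0("B", seq_len(config$n_b_founders))
  c_id <- paste0("C", seq_len(config$n_c_founders))
  d_id <- paste0("D", seq_len(config$n_dams))
  d_sire <- sample(b_id, config$n_dams, replace = TRUE)
  d_dam <- sample(c_id, config$n_dams, replace = TRUE)
  # spread F1 dams evenly over the A sires
  sire_of_dam <- sample(rep(a_id, length.out = config$n_dams))

  n_x <- config$n_dams * config$offspring_per_mating
  x_id <- paste0("X", seq_len(n_x))
  x_dam <- rep(d_id, each = config$offspring_per_mating)
  x_sire <- rep(sire_of_dam, each = config$offspring_per_mating)

  pens_per_batch <- config$n_pens %/% config$n_batches
  dam_batch <- sample(config$n_batches, config$n_dams, replace = TRUE)
  x_batch <- rep(dam_batch, each = config$offspring_per_mating)
  # sire's primary pen within each batch
  primary <- matrix(sample(pens_per_batch,
                           config$n_sires * config$n_batches, replace = TRUE),
                    config$n_sires, config$n_batches,
                    dimnames = list(a_id, NULL))
  x_sire_idx <- match(x_sire, a_id)
  pen_in_batch <- ifelse(stats::runif(n_x) < config$pen_fidelity,
                         primary[cbind(x_sire_idx, x_batch)],
                         sample(pens_per_batch, n_x, replace = TRUE))
  x_pen <- (x_batch - 1L) * pens_per_batch + pen_in_batch
  x_sex <- sample(c("M", "F"), n_x, replace = TRUE)

  animal <- c(gs_id, gd_id, a_id, b_id, c_id, d_id, x_id)
  n_gp <- length(gs_id) + length(gd_id)
  sire <- c(rep("0", n_gp), a_sire,
            rep("0", length(b_id) + length(c_id)), d_sire, x_sire)
  dam <- c(rep("0", n_gp), a_dam,
           rep("0", length(b_id) + length(c_id)), d_dam, x_dam)
  ped <- pedigree(animal, sire, dam)
  type <- c(rep("GP_A", n_gp), rep("SIRE_A", length(a_id)),
            rep("FOUNDER_B", length(b_id)), rep("FOUNDER_C", length(c_id)),
            rep("DAM_F1", length(d_id)), rep("CROSS", n_x))
  meta <- data.frame(animal = animal, type = type, sire = sire, dam = dam,
                     batch = c(rep(NA_integer_, length(animal) - n_x), x_batch),
                     pen = c(rep(NA_integer_, length(animal) - n_x), x_pen),
                     sex = c(rep(NA_character_, length(animal) - n_x), x_sex),
                     stringsAsFactors = FALSE)
  meta$fixed <- ifelse(meta$type == "CROSS",
                       paste0("p", meta$pen, "_", meta$sex), NA)
  founder_breed <- stats::setNames(
    c(rep("A", n_gp), rep("B", length(b_id)), rep("C", length(c_id))),
    c(gs_id, gd_id, b_id, c_id))
  list(ped = ped, meta = meta, founder_breed = founder_breed)
}

#' Mendelian gene dropping with breed-of-origin tracking
#'
#' Founders draw two haplotypes in Hardy-Weinberg proportions from their
#' breed's allele frequencies; every other animal inherits one random
#' allele per parent per SNP. Each allele carries its breed of origin, so
#' true genome-based breed fractions fall out as allele counts: a
#' crossbred's paternal gamete is pure sire-breed (fraction exactly 0.5)
#' and its two dam-breed fractions sum to 0.5.
#'
#' @param ped a [pedigree()]; every parentless animal must appear in
#'   `founder_breed`.
#' @param founder_breed named vector animal -> breed (A/B/C).
#' @param p_breed 3 x n_snps matrix of breed allele frequencies
#'   (rows A, B, C).
#' @param seed optional seed.
#' @return list with `geno` (dosage matrix, animals x SNPs) and
#'   `frac_true` (animals x 3 matrix of true breed fractions).
#' @export
gene_drop <- function(ped, founder_breed, p_breed, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ped, "jf_ped"))
  m <- ncol(p_breed)
  n <- ped$n
  breeds <- c("A", "B", "C")
  hap_s <- matrix(0L, n, m)   # gamete received from the sire side
  hap_d <- matrix(0L, n, m)   # gamete received from the dam side
  org_s <- matrix(0L, n, m)
  org_d <- matrix(0L, n, m)
  bix <- match(founder_breed, breeds)
  names(bix) <- names(founder_breed)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (s == 0L && d == 0L) {
      b <- bix[[ped$id[i]]]
      if (is.na(b)) stop("founder ", ped$id[i], " has no breed assignment")
      pf <- p_breed[b, ]
      hap_s[i, ] <- stats::rbinom(m, 1L, pf)
      hap_d[i, ] <- stats::rbinom(m, 1L, pf)
      org_s[i, ] <- b
      org_d[i, ] <- b
    } else if (s > 0L && d > 0L) {
      pick <- stats::runif(m) < 0.5
      hap_s[i, ] <- ifelse(pick, hap_s[s, ], hap_d[s, ])
      org_s[i, ] <- ifelse(pick, org_s[s, ], org_d[s, ])
      pick <- stats::runif(m) < 0.5
      hap_d[i, ] <- ifelse(pick, hap_s[d, ], hap_d[d, ])
      org_d[i, ] <- ifelse(pick, org_s[d, ], org_d[d, ])
    } else {
      stop("animal ", ped$id[i], " has exactly one known parent; ",
           "the generator requires founders or full parentage")
    }
  }
  geno <- hap_s + hap_d
  dimnames(geno) <- list(ped$id, paste0("snp", seq_len(m)))
  frac <- sapply(1:3, function(b) {
    (rowSums(org_s == b) + rowSums(org_d == b)) / (2 * m)
  })
  dimnames(frac) <- list(ped$id, breeds)
  list(geno = geno, frac_true = frac)
}

#' Simulate phenotypes under the additive + maternal model
#'
#' True breeding values are the sum of SNP effects and a
#' pedigree-correlated residual polygenic term of variance
#' `w_true * var_a` (simulated by Mendelian-sampling recursion with
#' inbreeding-adjusted segregation variance). SNP effects are drawn
#' i.i.d. normal with variance
#' `var_a (1 - w_true) / sum_o (pA(1-pA) + pm(1-pm))`, where `pA` is the
#' sire-breed frequency and `pm` the mean dam-breed frequency of SNP `o`:
#' the expected additive variance in the crossbred generation — where the
#' variance components are defined — then matches `var_a` (a plain
#' `2 sum p(1-p)` at pooled base frequencies would understate it under
#' divergent lines, by roughly `1 - 0.75 F_ST`). Phenotypes of crossbreds
#' add a per-level fixed effect, the dam's permanent environmental
#' effect, and an i.i.d. residual.
#'
#' @param ped a [pedigree()].
#' @param geno dosage matrix from [gene_drop()].
#' @param meta metadata from [build_cross_pedigree()].
#' @param config a [sim_config()].
#' @param p_breed 3 x n_snps matrix of breed allele frequencies (rows A,
#'   B, C); genotypes are centred at their pooled mean.
#' @param seed optional seed.
#' @return list with `pheno` (data.frame `animal`, `y`, `fixed`, `dam`,
#'   `sire`, `batch`, `pen`, `sex` for crossbreds) and `truth` (list with
#'   `u`, `snp_effects`, `maternal`, `fixed_effects`, `inbreeding`).
#' @export
simulate_phenotypes <- function(ped, geno, meta, config, p_breed,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(geno)
  var_snp_total <- config$var_a * (1 - config$w_true)
  p_pat <- p_breed["A", ]
  p_mat <- (p_breed["B", ] + p_breed["C", ]) / 2
  denom <- sum(p_pat * (1 - p_pat) + p_mat * (1 - p_mat))
  alpha <- stats::rnorm(m, 0, sqrt(var_snp_total / denom))
  p_base <- colMeans(p_breed)
  Zc <- sweep(geno, 2, 2 * p_base, "-")
  u_snp <- drop(Zc %*% alpha)

  # residual polygenic term: Mendelian-sampling recursion
  var_poly <- config$w_true * config$var_a
  Fcoef <- inbreeding(ped)
  a_poly <- numeric(ped$n)
  if (var_poly > 0) {
    for (i in seq_len(ped$n)) {
      s <- ped$sire[i]
      d <- ped$dam[i]
      if (s == 0L && d == 0L) {
        a_poly[i] <- stats::rnorm(1, 0, sqrt(var_poly))
      } else {
        pa <- 0
        vm <- 1
        if (s > 0L) {
          pa <- pa + 0.5 * a_poly[s]
          vm <- vm - 0.25 * (1 + Fcoef[s])
        }
        if (d > 0L) {
          pa <- pa + 0.5 * a_poly[d]
          vm <- vm - 0.25 * (1 + Fcoef[d])
        }
        a_poly[i] <- pa + stats::rnorm(1, 0, sqrt(var_poly * vm))
      }
    }
  }
  u <- u_snp + a_poly
  names(u) <- ped$id

  dams <- unique(meta$dam[meta$type == "CROSS"])
  c_dam <- stats::setNames(stats::rnorm(length(dams), 0, sqrt(config$var_c)),
                           dams)
  cross <- meta[meta$type == "CROSS", , drop = FALSE]
  levels_fx <- sort(unique(cross$fixed))
  fx <- stats::setNames(stats::rnorm(length(levels_fx), 0, config$fixed_sd),
                        levels_fx)
  e <- stats::rnorm(nrow(cross), 0, sqrt(config$var_e))
  y <- config$trait_mean + fx[cross$fixed] + u[cross$animal] +
    c_dam[cross$dam] + e
  pheno <- data.frame(animal = cross$animal, y = unname(y),
                      fixed = cross$fixed, dam = cross$dam,
                      sire = cross$sire, batch = cross$batch,
                      pen = cross$pen, sex = cross$sex,
                      stringsAsFactors = FALSE)
  list(pheno = pheno,
       truth = list(u = u, snp_effects = alpha, maternal = c_dam,
                    fixed_effects = fx, inbreeding = Fcoef))
}

#' Simulate a complete three-way crossbred dataset
#'
#' Runs the full generator: divergent founder lines, the crossing
#' pedigree, gene dropping with breed-of-origin tracking, observed breed
#' fractions (true fractions plus truncated normal noise, then scaled via
#' [scale_observed_fractions()]), pedigree-expected fractions, and
#' phenotypes. A fixed configuration (including its seed) reproduces the
#' dataset exactly.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `ped`, `meta`, `founder_breed`, `geno`,
#'   `p_breed`, `p_base`, `frac_true`, `Q_exp` (expected fractions, all
#'   animals), `Q_obs` (scaled observed fractions of the crossbreds),
#'   `pheno`, `truth`.
#' @export
simulate_crossbred_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freqs <- simulate_founder_breeds(config, seed = NULL)
  pop <- build_cross_pedigree(config, seed = NULL)
  gd <- gene_drop(pop$ped, pop$founder_breed, freqs$p_breed, seed = NULL)
  p_base <- colMeans(freqs$p_breed)
  sim_ph <- simulate_phenotypes(pop$ped, gd$geno, pop$meta, config,
                                freqs$p_breed, seed = NULL)
  Q_exp <- expected_breed_fractions(pop$ped, pop$founder_breed,
                                    breeds = c("A", "B", "C"))
  cross_ids <- pop$meta$animal[pop$meta$type == "CROSS"]
  raw_obs <- gd$frac_true[cross_ids, , drop = FALSE] +
    matrix(stats::rnorm(length(cross_ids) * 3, 0, config$frac_noise_sd),
           ncol = 3)
  raw_obs <- pmax(raw_obs, 0)
  Q_obs <- scale_observed_fractions(raw_obs)
  dimnames(Q_obs) <- list(cross_ids, c("A", "B", "C"))
  # purebred genotyped animals keep unit rows: their breed is known
  pure_ids <- pop$meta$animal[pop$meta$type %in%
                                c("SIRE_A", "FOUNDER_B", "FOUNDER_C")]
  Q_obs <- rbind(Q_exp[pure_ids, , drop = FALSE], Q_obs)
  list(config = config, ped = pop$ped, meta = pop$meta,
       founder_breed = pop$founder_breed, geno = gd$geno,
       p_breed = freqs$p_breed, p_base = p_base,
       frac_true = gd$frac_true, Q_exp = Q_exp, Q_obs = Q_obs,
       pheno = sim_ph$pheno, truth = sim_ph$truth)
}
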