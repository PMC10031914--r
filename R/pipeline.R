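#' Evaluate one genotyping scenario within one cross-validation fold
#'
#' Removes the fold's validation offspring from the reference population,
#' selects the genotyped subset of the remaining crossbreds at the given
#' rate and scheme, builds the J covariates requested, solves the
#' single-step model, and scores the validation sires' GEBV against their
#' corrected progeny means with reliability weights.
#'
#' The purebred A sires are genotyped throughout and enter Q with unit
#' rows; the genotyping rate and scheme act on the reference crossbreds
#' only, whose discarded genotypes mimic the selective genotyping
#' designs. The maternal line (F1 dams and their founders) stays
#' ungenotyped, so below a 100% rate the single J covariate varies over
#' phenotyped animals and its coefficient is estimable, while at 100%
#' every phenotyped animal is genotyped, the covariate is constant at -1,
#' and the J coefficient is confounded with the general mean (dropped
#' with a flag, reproducing the no-J model exactly). With expected breed
#' fractions the two dam-breed covariate columns are exactly collinear
#' (both dam fractions are 0.25 for every genotyped crossbred), so one of
#' them is dropped as aliased; the fit and GEBV are unaffected.
#'
#' @param sim a dataset from [simulate_crossbred_population()] (or any
#'   list with the same elements).
#' @param val_sires sires whose offspring form the validation set.
#' @param rate genotyping rate (1, 0.75, 0.5, 0.25).
#' @param scheme `"RND"` or `"TOP"`.
#' @param j_method one of `"NONE"`, `"ONE"`, `"EXP"`, `"OBS"`.
#' @param varcomp list with `var_a`, `var_c`, `var_e`.
#' @param w residual polygenic proportion (default 0.05).
#' @param spm sire progeny means from [sire_progeny_means()] (computed on
#'   the full data); recomputed if `NULL`.
#' @param A optional precomputed `a_matrix(sim$ped)`.
#' @param A_inv optional precomputed inverse of `A` (pedigree order).
#' @param seed seed for the genotype-selection draw.
#' @return list with `accuracy`, `slope2`, `gebv` (validation sires),
#'   `j_coef`, `genotyped`, `solutions`.
#' @export
evaluate_scenario <- function(sim, val_sires, rate, scheme, j_method,
                              varcomp, w = 0.05, spm = NULL,
                              A = NULL, A_inv = NULL, seed = 1) {
  j_method <- match.arg(j_method, c("NONE", "ONE", "EXP", "OBS"))
  ped <- sim$ped
  pheno <- sim$pheno
  val_sires <- as.character(val_sires)
  ref <- pheno[!(pheno$sire %in% val_sires), , drop = FALSE]
  genotyped_cross <- apply_genotyping_scheme(ref$animal, rate, scheme,
                                             phenotype = ref$y, seed = seed)
  pure <- sim$meta$animal[sim$meta$type == "SIRE_A"]
  genotyped <- c(pure, genotyped_cross)
  if (is.null(A)) A <- a_matrix(ped)
  if (is.null(A_inv)) A_inv <- chol2inv(chol(A))
  dimnames(A_inv) <- dimnames(A)
  part <- rel_partition(ped, genotyped, A = A)

  M <- sim$geno[part$genotyped, , drop = FALSE]
  cg <- center_genotypes(M)
  G <- build_G(cg$Z, build_B(cg$p, w), w, part$A_gg)
  K_inv <- h_inverse(part, G,
                     A_inv = A_inv[part$order, part$order])

  J <- switch(j_method,
    NONE = NULL,
    ONE = jfactor_direct(part),
    EXP = jfactor_direct(part, structure(
      sim$Q_exp[part$genotyped, , drop = FALSE], source_tag = "EXP")),
    OBS = jfactor_direct(part, structure(
      sim$Q_obs[part$genotyped, , drop = FALSE], source_tag = "OBS")))

  solutions <- withCallingHandlers(
    solve_mme(ref, K_inv, varcomp, J = J),
    warning = function(wrn) {
      if (grepl("aliased", conditionMessage(wrn))) {
        invokeRestart("muffleWarning")
      }
    })

  if (is.null(spm)) {
    h2 <- varcomp$var_a / (varcomp$var_a + varcomp$var_c + varcomp$var_e)
    spm <- sire_progeny_means(pheno, h2)
  }
  rec <- spm[spm$sire %in% val_sires, , drop = FALSE]
  gebv_s <- solutions$gebv[rec$sire]
  list(accuracy = weighted_cor(gebv_s, rec$progeny_mean, rec$reliability),
       slope2 = dispersion_slope(gebv_s, rec$progeny_mean, rec$reliability),
       gebv = gebv_s,
       j_coef = solutions$j_coef,
       genotyped = genotyped,
       solutions = solutions)
}

#' Run the scenario grid over replicates and folds
#'
#' For each replicate a fresh population is simulated (replicate seeds are
#' derived from the root seed), sires are split into cross-validation
#' folds, and every requested (rate, scheme, J-method) cell is evaluated
#' within each fold. Validation statistics are computed within folds. A
#' `NONE` cell at a genotyping rate of 100% duplicates `ONE` (the single
#' J-factor is confounded with the general mean there) and is skipped with
#' a message when both are requested.
#'
#' @param config a [sim_config()] describing the population of every
#'   replicate (the replicate seed is added to its seed).
#' @param varcomp list with `var_a`, `var_c`, `var_e`; defaults to the
#'   generator's components.
#' @param w residual polygenic proportion (default 0.05).
#' @param j_methods,rates,schemes grid selections.
#' @param replicates number of simulation replicates.
#' @param k_folds cross-validation folds per replicate.
#' @param folds_use optionally evaluate only the first so-many folds of
#'   each replicate (all by default).
#' @param seed root seed; every random stage derives from it.
#' @return list of class `jf_grid` with `cells` (one row per
#'   replicate x fold x scenario: `rate`, `scheme`, `j_method`,
#'   `replicate`, `fold`, `accuracy`, `slope2`), `j_coefficients`, and
#'   `j_covariates` (mean covariates of phenotyped genotyped-set scenarios
#'   per breed).
#' @export
run_scenarios <- function(config = sim_config(),
                          varcomp = NULL, w = 0.05,
                          j_methods = c("NONE", "ONE", "EXP", "OBS"),
                          rates = c(1, 0.75, 0.5, 0.25),
                          schemes = c("RND", "TOP"),
                          replicates = 1, k_folds = 5, folds_use = NULL,
                          seed = 1) {
  if (is.null(varcomp)) {
    varcomp <- list(var_a = config$var_a, var_c = config$var_c,
                    var_e = config$var_e)
  }
  h2 <- varcomp$var_a / (varcomp$var_a + varcomp$var_c + varcomp$var_e)
  if (is.null(folds_use)) folds_use <- k_folds
  cells <- list()
  jcoefs <- list()
  jcovs <- list()
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- (seed + 7919L * rep_i) %% .Machine$integer.max
    sim <- simulate_crossbred_population(cfg)
    A <- a_matrix(sim$ped)
    A_inv <- chol2inv(chol(A))
    dimnames(A_inv) <- dimnames(A)
    spm <- sire_progeny_means(sim$pheno, h2)
    sires <- unique(sim$pheno$sire)
    folds <- make_folds(sires, k = k_folds, seed = cfg$seed + 1L)
    for (fold_i in seq_len(folds_use)) {
      val_sires <- names(folds)[folds == fold_i]
      for (rate in rates) for (scheme in schemes) for (jm in j_methods) {
        if (jm == "NONE" && rate == 1 && "ONE" %in% j_methods) {
          message("NONE at 100% genotyping duplicates ONE; skipped")
          next
        }
        res <- evaluate_scenario(sim, val_sires, rate, scheme, jm,
                                 varcomp, w = w, spm = spm,
                                 A = A, A_inv = A_inv,
                                 seed = cfg$seed + 100L * fold_i +
                                   round(1000 * rate) +
                                   (scheme == "TOP"))
        cells[[length(cells) + 1L]] <- data.frame(
          rate = rate, scheme = scheme, j_method = jm,
          replicate = rep_i, fold = fold_i,
          accuracy = res$accuracy, slope2 = res$slope2,
          stringsAsFactors = FALSE)
        if (!is.null(res$j_coef)) {
          jcoefs[[length(jcoefs) + 1L]] <- data.frame(
            rate = rate, scheme = scheme, j_method = jm,
            replicate = rep_i, fold = fold_i,
            coef = names(res$j_coef), estimate = unname(res$j_coef),
            stringsAsFactors = FALSE)
        }
        if (jm %in% c("EXP", "OBS", "ONE")) {
          Jfull <- switch(jm,
            ONE = jfactor_direct(rel_partition(sim$ped, res$genotyped, A = A)),
            EXP = jfactor_direct(rel_partition(sim$ped, res$genotyped, A = A),
                                 sim$Q_exp[res$genotyped, , drop = FALSE]),
            OBS = jfactor_direct(rel_partition(sim$ped, res$genotyped, A = A),
                                 sim$Q_obs[res$genotyped, , drop = FALSE]))
          ph_ids <- sim$pheno$animal
          jcovs[[length(jcovs) + 1L]] <- data.frame(
            rate = rate, scheme = scheme, j_method = jm,
            replicate = rep_i, fold = fold_i,
            breed = colnames(Jfull),
            mean_covariate = colMeans(Jfull[ph_ids, , drop = FALSE]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 j_coefficients = do.call(rbind, jcoefs),
                 j_covariates = do.call(rbind, jcovs)),
            class = "jf_grid")
}

#' Summarize scenario cells across replicates and folds
#'
#' Mean and SD of accuracy and doubled regression slope per
#' (rate, scheme, J-method) cell, with two-decimal rounded report columns
#' (half away from zero).
#'
#' @param grid result of [run_scenarios()], or its `cells` data.frame.
#' @return data.frame, one row per cell.
#' @export
summarize_scenarios <- function(grid) {
  cells <- if (inherits(grid, "jf_grid")) grid$cells else grid
  key <- interaction(cells$rate, cells$scheme, cells$j_method, drop = TRUE)
  out <- do.call(rbind, lapply(split(cells, key), function(d) {
    data.frame(rate = d$rate[1], scheme = d$scheme[1],
               j_method = d$j_method[1],
               n = nrow(d),
               accuracy_mean = mean(d$accuracy, na.rm = TRUE),
               accuracy_sd = stats::sd(d$accuracy, na.rm = TRUE),
               slope2_mean = mean(d$slope2, na.rm = TRUE),
               slope2_sd = stats::sd(d$slope2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out$accuracy_rep <- round_half_away(out$accuracy_mean)
  out$slope2_rep <- round_half_away(out$slope2_mean)
  out <- out[order(-out$rate, out$scheme, out$j_method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pipeline run configuration
#'
#' YAML file with (all optional) keys `seed`, `replicates`, `k_folds`,
#' `folds_use`, `rates`, `schemes`, `j_methods`, `w`, `out_dir`,
#' `varcomp` (`var_a`/`var_c`/`var_e`) and `sim` (overrides passed to
#' [sim_config()]).
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "replicates", "k_folds", "folds_use", "rates",
               "schemes", "j_methods", "w", "out_dir", "varcomp", "sim")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$rates)) cfg$rates <- as.numeric(cfg$rates)
  cfg
}

#' Run the full pipeline and write result tables
#'
#' Simulates, computes J-factors, solves the single-step models over the
#' requested scenario grid, and writes tab-separated tables to `out_dir`:
#' per-cell results (`scenario_results.tsv`), their summary
#' (`scenario_summary.tsv`), mean J covariates per breed
#' (`j_covariates.tsv`), estimated J regression coefficients
#' (`j_coefficients.tsv`), and a run log with seed and per-stage timing.
#'
#' @param config list as from [read_run_config()] (or a path to a YAML
#'   file).
#' @return (invisibly) the [run_scenarios()] result.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir %||% "jfblup_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  sim_cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ..., "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logline("jfblup", as.character(utils::packageVersion("jfblup")),
          "| root seed", seed)
  t0 <- Sys.time()
  grid <- run_scenarios(
    config = sim_cfg,
    varcomp = config$varcomp,
    w = config$w %||% 0.05,
    j_methods = config$j_methods %||% c("NONE", "ONE", "EXP", "OBS"),
    rates = config$rates %||% c(1, 0.75, 0.5, 0.25),
    schemes = config$schemes %||% c("RND", "TOP"),
    replicates = config$replicates %||% 1,
    k_folds = config$k_folds %||% 5,
    folds_use = config$folds_use,
    seed = seed)
  logline("scenario grid done in",
          format(difftime(Sys.time(), t0, units = "secs"), digits = 3))
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(grid$cells, "scenario_results.tsv")
  wt(summarize_scenarios(grid), "scenario_summary.tsv")
  if (!is.null(grid$j_covariates)) wt(grid$j_covariates, "j_covariates.tsv")
  if (!is.null(grid$j_coefficients)) {
    wt(grid$j_coefficients, "j_coefficients.tsv")
  }
  logline("tables written to", normalizePath(out_dir))
  invisible(grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
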