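# small hand-built Henderson system as an independent oracle
mme_oracle <- function(y, Fmat, Zmat, Kinv, lambda) {
  C <- rbind(cbind(crossprod(Fmat), crossprod(Fmat, Zmat)),
             cbind(crossprod(Zmat, Fmat),
                   crossprod(Zmat) + lambda * Kinv))
  rhs <- c(crossprod(Fmat, y), crossprod(Zmat, y))
  solve(C, rhs)
}

test_that("animal-model solutions match a hand-built Henderson system", {
  ped <- rand_pedigree(12, seed = 1, p_unknown = 0.2)$ped
  A <- a_matrix(ped)
  Kinv <- chol2inv(chol(A))
  dimnames(Kinv) <- dimnames(A)
  set.seed(2)
  rec <- data.frame(animal = sample(ped$id, 9),
                    fixed = sample(c("l1", "l2"), 9, replace = TRUE))
  rec$y <- rnorm(9, 10)
  vc <- list(var_a = 2, var_e = 3)
  sol <- solve_mme(rec, Kinv, vc)
  Fm <- model.matrix(~ 0 + factor(rec$fixed))
  Zm <- matrix(0, 9, 12)
  Zm[cbind(1:9, match(rec$animal, ped$id))] <- 1
  ref <- mme_oracle(rec$y, Fm, Zm, Kinv, vc$var_e / vc$var_a)
  expect_equal(unname(sol$fixed), unname(ref[1:2]), tolerance = 1e-10)
  expect_equal(unname(sol$u), unname(ref[-(1:2)]), tolerance = 1e-10)
  expect_lt(sol$residual, 1e-8)
})

test_that("single-record shrinkage follows the closed form", {
  # two unrelated animals sharing one level: the mean absorbs the average
  # and each deviation is shrunk by 1/(1 + lambda)
  ped <- pedigree(c("a", "b"), c(0, 0), c(0, 0))
  A <- diag(2); dimnames(A) <- list(ped$id, ped$id)
  vc <- list(var_a = 1, var_e = 3)
  rec <- data.frame(animal = c("a", "b"), fixed = "m", y = c(2, -2))
  sol <- solve_mme(rec, A, vc)
  lambda <- vc$var_e / vc$var_a
  expect_equal(unname(sol$u["a"]), 2 / (1 + lambda), tolerance = 1e-10)
  expect_equal(unname(sol$u["b"]), -2 / (1 + lambda), tolerance = 1e-10)
  expect_equal(unname(sol$fixed), 0, tolerance = 1e-10)
})

test_that("maternal permanent environment block shrinks dam means", {
  sim <- small_sim(seed = 5)
  ped <- sim$ped
  A <- a_matrix(ped)
  Kinv <- chol2inv(chol(A)); dimnames(Kinv) <- dimnames(A)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  sol <- solve_mme(sim$pheno, Kinv, vc)
  expect_equal(sort(names(sol$pe)), sort(unique(sim$pheno$dam)))
  # permanent environmental estimates correlate with the simulated truth
  truth <- sim$truth$maternal[names(sol$pe)]
  expect_gt(cor(sol$pe, truth), 0.3)
  expect_lt(sol$residual, 1e-8)
})

test_that("phenotype shift moves fixed effects, not breeding-value contrasts", {
  sim <- small_sim(seed = 6)
  A <- a_matrix(sim$ped)
  Kinv <- chol2inv(chol(A)); dimnames(Kinv) <- dimnames(A)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  part <- rel_partition(sim$ped, sim$pheno$animal[1:60], A = A)
  J <- jfactor_direct(part)
  s1 <- solve_mme(sim$pheno, Kinv, vc, J = J)
  ph2 <- sim$pheno
  ph2$y <- ph2$y + 50
  s2 <- solve_mme(ph2, Kinv, vc, J = J)
  expect_equal(s2$fixed - s1$fixed, rep(50, length(s1$fixed)),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(s2$gebv - mean(s2$gebv), s1$gebv - mean(s1$gebv),
               tolerance = 1e-6)
})

test_that("GEBV of a genotyped animal with one J equals u_hat minus mu_hat", {
  sim <- small_sim(seed = 7)
  A <- a_matrix(sim$ped)
  g <- sim$pheno$animal[1:50]
  part <- rel_partition(sim$ped, g, A = A)
  M <- sim$geno[part$genotyped, ]
  cg <- suppressWarnings(center_genotypes(M))
  G <- build_G(cg$Z, build_B(cg$p, 0.05), 0.05, part$A_gg)
  Kinv <- h_inverse(part, G)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  J <- jfactor_direct(part)
  sol <- solve_mme(sim$pheno, Kinv, vc, J = J)
  gid <- part$genotyped[1]
  expect_equal(unname(sol$gebv[gid]),
               unname(sol$u[gid]) - unname(sol$j_coef["J"]),
               tolerance = 1e-8)
})

test_that("w = 1 single-step reduces to pedigree BLUP", {
  sim <- small_sim(seed = 8)
  A <- a_matrix(sim$ped)
  Kinv_A <- chol2inv(chol(A)); dimnames(Kinv_A) <- dimnames(A)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  ped_sol <- solve_mme(sim$pheno, Kinv_A, vc)
  g <- sim$pheno$animal[1:40]
  part <- rel_partition(sim$ped, g, A = A)
  G1 <- build_G(matrix(0, 40, 1), 0, 1, part$A_gg)   # w = 1: G = A_gg
  Kinv_H <- h_inverse(part, G1)
  ss_sol <- solve_mme(sim$pheno, Kinv_H, vc)
  expect_equal(ss_sol$u[names(ped_sol$u)], ped_sol$u, tolerance = 1e-6)

  snp_sol <- suppressWarnings(
    solve_snp_level(sim$pheno, part, sim$geno[g, ], w = 1, vc))
  expect_equal(snp_sol$u[names(ped_sol$u)], ped_sol$u, tolerance = 1e-6)
  expect_true(all(snp_sol$snp == 0))
})

test_that("SNP-level parameterization is equivalent to the H-matrix solve", {
  for (seed in 1:6) {
    ped <- rand_pedigree(10, seed = seed, p_unknown = 0.2)$ped
    A <- a_matrix(ped)
    g <- sample(ped$id, 5)
    part <- rel_partition(ped, g, A = A)
    set.seed(seed + 300)
    M <- matrix(rbinom(5 * 20, 2, runif(20, 0.2, 0.8)), 5,
                dimnames = list(part$genotyped, paste0("s", 1:20)))
    rec <- data.frame(animal = sample(ped$id, 8, replace = TRUE),
                      fixed = sample(c("u", "v"), 8, replace = TRUE))
    rec$y <- rnorm(8, 5, 2)
    vc <- list(var_a = 1.5, var_e = 2.5)
    w <- 0.05
    cg <- suppressWarnings(center_genotypes(M))
    G <- build_G(cg$Z, build_B(cg$p, w), w, part$A_gg)
    h_sol <- solve_mme(rec, h_inverse(part, G), vc)
    s_sol <- suppressWarnings(solve_snp_level(rec, part, M, w, vc))
    expect_equal(s_sol$u[names(h_sol$u)], h_sol$u, tolerance = 1e-6)
    expect_equal(s_sol$fixed, h_sol$fixed, tolerance = 1e-6)
    # the marker part of u_g is exactly Z g plus the polygenic residual
    expect_equal(unname(s_sol$u[part$genotyped] - s_sol$poly),
                 unname(drop(cg$Z %*% s_sol$snp)), tolerance = 1e-6)
  }
})

test_that("confounded J columns are dropped with a warning and flagged", {
  sim <- small_sim(seed = 9)
  A <- a_matrix(sim$ped)
  # every phenotyped animal genotyped: single J constant at -1
  part <- rel_partition(sim$ped, sim$pheno$animal, A = A)
  M <- sim$geno[part$genotyped, ]
  cg <- suppressWarnings(center_genotypes(M))
  G <- build_G(cg$Z, build_B(cg$p, 0.05), 0.05, part$A_gg)
  Kinv <- h_inverse(part, G)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  J <- jfactor_direct(part)
  expect_warning(sol <- solve_mme(sim$pheno, Kinv, vc, J = J), "aliased")
  expect_false(sol$j_estimable[["J"]])
  expect_true(is.na(sol$j_coef[["J"]]))
  sol0 <- solve_mme(sim$pheno, Kinv, vc)
  expect_equal(sol$gebv, sol0$gebv, tolerance = 1e-10)
})

test_that("solutions tables are written alongside J coefficients", {
  sim <- small_sim(seed = 10)
  A <- a_matrix(sim$ped)
  Kinv <- chol2inv(chol(A)); dimnames(Kinv) <- dimnames(A)
  part <- rel_partition(sim$ped, sim$pheno$animal[1:30], A = A)
  J <- jfactor_direct(part)
  vc <- list(var_a = sim$config$var_a, var_c = sim$config$var_c,
             var_e = sim$config$var_e)
  sol <- solve_mme(sim$pheno, Kinv, vc, J = J)
  dir <- withr::local_tempdir()
  paths <- write_solutions(sol, dir)
  tab <- read.delim(file.path(dir, "solutions.tsv"))
  expect_equal(nrow(tab), sim$ped$n)
  expect_true(file.exists(file.path(dir, "j_coefficients.tsv")))
})
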