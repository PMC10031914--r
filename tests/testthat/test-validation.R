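test_that("outlier filter removes only extreme deviations per group", {
  ph <- data.frame(y = rep(5, 30), group = "d1")
  expect_equal(nrow(outlier_filter(ph)), 30)

  set.seed(1)
  ph <- data.frame(y = rnorm(100), group = "d1")
  ph$y[7] <- 10 * sd(ph$y[-7])
  out <- outlier_filter(ph)
  expect_equal(nrow(out), 99)
  expect_false(any(out$y == ph$y[7]))
})

test_that("boundary records at exactly 3.5 SD survive the filter", {
  # construct a group whose sd and mean are known after including the probe
  y <- c(-2, -1, 0, 1, 2, 0, 0, 0)
  ph <- data.frame(y = y, group = "g")
  s <- sd(y); m <- mean(y)
  probe <- m + 3.5 * s
  # filtering uses the group statistics of the provided records
  ph2 <- rbind(ph, data.frame(y = probe, group = "g"))
  s2 <- sd(ph2$y); m2 <- mean(ph2$y)
  out <- outlier_filter(ph2)
  expect_equal(sum(abs(out$y - m2) > 3.5 * s2), 0)
  # single-record groups warn and are kept
  expect_warning(out2 <- outlier_filter(
    data.frame(y = c(1, 1e6), group = c("a", "b"))), "size 1")
  expect_equal(nrow(out2), 2)
})

test_that("SNP QC drops low-MAF and Mendelian-inconsistent markers", {
  fx <- three_way_fixture(n_sires = 4, n_dams = 10, n_off = 5, seed = 3)
  ids <- c(fx$sires, fx$crossbreds)
  n <- length(ids)
  # s1 and s4..s6 are Mendelian-clean: constant heterozygotes
  M <- matrix(1, n, 6, dimnames = list(ids, paste0("s", 1:6)))
  # s2: rare allele (MAF < 0.005)
  M[, 2] <- 0; M[1, 2] <- 1   # MAF = 1/(2n) < 0.005 for n > 100? here small
  maf2 <- min(mean(M[, 2]) / 2, 1 - mean(M[, 2]) / 2)
  # s3: systematic opposing homozygotes between sires and offspring
  sire_rows <- match(fx$sires, ids)
  M[sire_rows, 3] <- 0
  M[-sire_rows, 3] <- 2
  kept <- snp_qc(M, fx$ped, maf_min = maf2 + 1e-9)
  expect_false("s2" %in% kept)
  expect_false("s3" %in% kept)
  expect_true("s1" %in% kept)

  # clean simulated data is fully retained
  sim <- small_sim(seed = 11)
  kept_all <- snp_qc(sim$geno, sim$ped, maf_min = 0.005)
  p <- colMeans(sim$geno) / 2
  informative <- pmin(p, 1 - p) >= 0.005
  expect_equal(kept_all, colnames(sim$geno)[informative])

  # call-rate filter only acts when missingness exists
  M2 <- M[, 1, drop = FALSE]
  M2[1:ceiling(0.1 * n), 1] <- NA
  expect_warning(kept2 <- snp_qc(M2, fx$ped, call_rate = 0.95),
                 NA)
  expect_equal(length(kept2), 0)
})

test_that("fold sizes differ by at most one and are seed-stable", {
  sires <- paste0("S", 1:161)
  f <- make_folds(sires, k = 5, seed = 42)
  expect_equal(as.integer(sort(table(f))), c(32L, 32L, 32L, 32L, 33L))
  expect_equal(f, make_folds(sires, k = 5, seed = 42))
  expect_false(all(f == make_folds(sires, k = 5, seed = 43)))
  expect_equal(as.integer(table(make_folds(paste0("S", 1:10), k = 5,
                                           seed = 1))), rep(2L, 5))
  expect_error(make_folds(paste0("S", 1:3), k = 5), "folds")
})

test_that("genotyping schemes select by chance or by merit", {
  a <- paste0("x", 1:10)
  expect_setequal(apply_genotyping_scheme(a, 1, "RND", seed = 1), a)
  top <- apply_genotyping_scheme(a, 0.5, "TOP", phenotype = 1:10, seed = 1)
  expect_setequal(top, a[6:10])
  r1 <- apply_genotyping_scheme(a, 0.5, "RND", seed = 5)
  expect_equal(r1, apply_genotyping_scheme(a, 0.5, "RND", seed = 5))
  expect_length(r1, 5)
  expect_error(apply_genotyping_scheme(a, 0.3, "RND"), "rate")
  expect_error(apply_genotyping_scheme(a, 0.5, "TOP"), "phenotype")
  # different traits yield different TOP sets on the same animals
  set.seed(9)
  t1 <- rnorm(10); t2 <- rnorm(10)
  expect_false(setequal(
    apply_genotyping_scheme(a, 0.5, "TOP", phenotype = t1, seed = 2),
    apply_genotyping_scheme(a, 0.5, "TOP", phenotype = t2, seed = 2)))
})

test_that("reliability formula reproduces its closed-form values", {
  expect_equal(round_half_away(cameron_reliability(2, 0.26)), 0.12)
  expect_equal(round_half_away(cameron_reliability(430, 0.26)), 0.97)
  expect_equal(round_half_away(cameron_reliability(404, 0.25)), 0.96)
  expect_equal(cameron_reliability(1, 0.3), 0.3 / 4)
  # strictly increasing in n and h2, limit 1
  n <- 1:500
  r <- cameron_reliability(n, 0.26)
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(cameron_reliability(100, seq(0.05, 0.95, 0.05))) > 0))
  expect_equal(cameron_reliability(1e8, 0.26), 1, tolerance = 1e-6)
})

test_that("progeny means are invariant to balanced fixed-effect shifts", {
  set.seed(6)
  sires <- rep(paste0("S", 1:6), each = 10)
  u_s <- rnorm(6, 0, 2)[match(sires, paste0("S", 1:6))]
  base <- u_s + rnorm(60)
  # balanced design: each sire has 5 offspring in each pen
  pen <- rep(rep(c("p1", "p2"), each = 5), 6)
  delta <- ifelse(pen == "p1", 7, -7)
  ph0 <- data.frame(sire = sires, fixed = pen, y = base)
  ph1 <- data.frame(sire = sires, fixed = pen, y = base + delta)
  r0 <- sire_progeny_means(ph0, h2 = 0.26)
  r1 <- sire_progeny_means(ph1, h2 = 0.26)
  expect_equal(r0$progeny_mean, r1$progeny_mean, tolerance = 1e-8)
  expect_equal(r0$reliability,
               cameron_reliability(r0$n_offspring, 0.26))
  # no fixed-effect variation: progeny means equal centred raw means
  ph2 <- data.frame(sire = sires, fixed = "one", y = base)
  r2 <- sire_progeny_means(ph2, h2 = 0.26)
  raw <- as.vector(tapply(base, sires, mean)[r2$sire])
  expect_equal(r2$progeny_mean - mean(r2$progeny_mean),
               raw - mean(raw), tolerance = 0.05)
  expect_gt(cor(r2$progeny_mean, raw), 0.999)
})

test_that("sires with too few offspring are excluded with a warning", {
  ph <- data.frame(sire = c(rep("S1", 5), "S2"),
                   fixed = "l", y = rnorm(6))
  expect_warning(r <- sire_progeny_means(ph, 0.25), "fewer than")
  expect_equal(r$sire, "S1")
})

test_that("weighted statistics reduce to unweighted at equal weights", {
  set.seed(7)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  expect_equal(weighted_cor(x, y, rep(2, 20)), cor(x, y))
  expect_equal(dispersion_slope(x, y, rep(3, 20)),
               2 * unname(coef(lm(y ~ x))[2]))
  expect_equal(weighted_cor(x, 2 * x), 1)
  expect_equal(dispersion_slope(x, 0.5 * x), 1)
  expect_equal(dispersion_slope(x, x), 2)
})

test_that("weighted statistics match brute-force weighted moments", {
  x <- c(1, 2, 4, 7)
  y <- c(0.5, 1.9, 3.1, 6.5)
  w <- c(0.1, 0.4, 0.3, 0.2)
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  cxy <- sum(wn * (x - mx) * (y - my))
  vx <- sum(wn * (x - mx)^2); vy <- sum(wn * (y - my)^2)
  expect_equal(weighted_cor(x, y, w), cxy / sqrt(vx * vy))
  expect_equal(dispersion_slope(x, y, w), 2 * cxy / vx)
  # 5-point slope example against the normal equations
  x5 <- c(x, 9); y5 <- c(y, 8.1); w5 <- c(w, 0.15)
  W <- diag(w5)
  X <- cbind(1, x5)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y5)
  expect_equal(dispersion_slope(x5, y5, w5), 2 * beta[2])
  # degenerate variance reported as missing
  expect_true(is.na(weighted_cor(rep(1, 4), y, w)))
  expect_true(is.na(dispersion_slope(rep(1, 4), y, w)))
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_away(0.125), 0.13)
  expect_equal(round_half_away(-0.125), -0.13)
  expect_equal(round_half_away(0.124), 0.12)
})
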