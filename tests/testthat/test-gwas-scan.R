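test_that("REML flags a constant phenotype as degenerate", {
  A <- founder_A(sprintf("s%02d", 1:10))
  z <- stats::setNames(rep(2.5, 10), rownames(A))
  vc <- fit_null_reml(z, A)
  expect_true(vc$degenerate)
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_e, 0)
})

test_that("REML optimum matches a dense grid search on a 5-sire instance", {
  ped <- data.frame(id = c("F", "S1", "S2", "S3", "S4"),
                    sire = c(NA, "F", "F", NA, NA), dam = NA)
  ids <- c("S1", "S2", "S3", "S4", "F")
  A <- build_A(ped, ids = ids)
  z <- withr::with_seed(19, stats::setNames(rnorm(5, 0, 1.3), ids))
  vc <- fit_null_reml(z, A)

  # independent oracle: profile restricted likelihood over a dense lambda
  # grid via explicit dense-matrix algebra
  grid <- 10^seq(-4, 4, length.out = 4000)
  ones <- rep(1, 5)
  ll <- sapply(grid, function(lam) {
    H <- lam * A + diag(5)
    Hi <- solve(H)
    xtx <- drop(crossprod(ones, Hi %*% ones))
    beta <- drop(crossprod(ones, Hi %*% z)) / xtx
    r <- z - beta
    s2e <- drop(crossprod(r, Hi %*% r)) / 4
    -0.5 * (4 * log(s2e) + determinant(H)$modulus + log(xtx) + 4)
  })
  best <- grid[which.max(ll)]
  # compare achieved restricted likelihoods (flat optima can differ in lambda)
  H <- vc$lambda * A + diag(5)
  Hi <- solve(H)
  xtx <- drop(crossprod(ones, Hi %*% ones))
  beta <- drop(crossprod(ones, Hi %*% z)) / xtx
  s2e <- drop(crossprod(z - beta, Hi %*% (z - beta))) / 4
  ll_fit <- -0.5 * (4 * log(s2e) + determinant(H)$modulus + log(xtx) + 4)
  expect_gte(ll_fit + 1e-6, max(ll))
  if (best > min(grid) * 1.01 && best < max(grid) * 0.99)
    expect_equal(log10(vc$lambda), log10(best), tolerance = 0.05)
})

test_that("a constant phenotype yields zero effects for every marker", {
  g <- founder_genotypes(20, c(0.2, 0.3, 0.4), seed = 23)
  A <- founder_A(rownames(g$dosage))
  z <- stats::setNames(rep(1, 20), rownames(A))
  vc <- structure(list(sigma2_g = 0, sigma2_e = 1, n = 20),
                  class = "variance_components")
  sc <- scan_snps(z, g, A, vc)
  expect_equal(sc$alpha, rep(0, 3), tolerance = 1e-12)
})

test_that("with no genetic variance the scan reduces to OLS", {
  g <- founder_genotypes(40, seq(0.1, 0.5, length.out = 8), seed = 29)
  A <- founder_A(rownames(g$dosage))
  z <- withr::with_seed(30, stats::setNames(rnorm(40), rownames(A)))
  vc <- structure(list(sigma2_g = 0, sigma2_e = 1, n = 40),
                  class = "variance_components")
  sc <- scan_snps(z, g, A, vc)
  for (j in seq_len(8)) {
    ols <- stats::coef(stats::lm(z ~ g$dosage[, j]))[[2]]
    expect_equal(sc$alpha[j], ols, tolerance = 1e-10)
  }
})

test_that("scan estimates equal the dense matrix-inverse GLS oracle", {
  for (s in 1:5) {
    n <- 8
    ped <- random_pedigree(n, seed = 40 + s)
    A <- build_A(ped)
    g <- withr::with_seed(50 + s, {
      d <- matrix(rbinom(n * 4, 2, 0.35), n, 4)
      d[1, 2] <- NA  # exercise the missing-dosage path
      genotype_matrix(d, data.frame(marker = paste0("m", 1:4), chr = "1",
                                    bp = (1:4) * 10L), ped$id)
    })
    z <- polygenic_means(A, 0.6, 0.8, seed = 60 + s)
    vc <- structure(list(sigma2_g = 0.6, sigma2_e = 0.8, n = n),
                    class = "variance_components")
    sc <- scan_snps(z, g, A, vc)
    V <- 0.6 * A + 0.8 * diag(n)
    for (j in 1:4) {
      use <- !is.na(g$dosage[, j])
      X <- cbind(1, g$dosage[use, j])
      if (stats::var(X[, 2]) == 0) next
      XtVi <- t(X) %*% solve(V[use, use])
      est <- solve(XtVi %*% X, XtVi %*% z[use])
      se <- sqrt(solve(XtVi %*% X)[2, 2])
      expect_equal(sc$alpha[j], est[2], tolerance = 1e-10)
      expect_equal(sc$se[j], se, tolerance = 1e-10)
    }
  }
})

test_that("Bonferroni level is the exact quotient", {
  expect_identical(bonferroni_level(0.05, 32), 0.05 / 32)
  expect_identical(bonferroni_level(0.05, 32), 0.0015625)
  expect_identical(bonferroni_level(0.05, 1), 0.05)
  expect_equal(bonferroni_level(0.05, 3681), 1.3583e-5, tolerance = 1e-3)
})

test_that("Monte-Carlo threshold calibrates against closed forms", {
  n <- 150
  A <- founder_A(sprintf("s%03d", 1:n))
  vc <- structure(list(sigma2_g = 0, sigma2_e = 1, n = n),
                  class = "variance_components")
  X <- withr::with_seed(71, matrix(rbinom(n * 30, 2, 0.3), n, 30))
  ids <- rownames(A)

  g1 <- genotype_matrix(X[, 1, drop = FALSE],
                        data.frame(marker = "a", chr = "1", bp = 1L), ids)
  thr1 <- chromosome_threshold(g1, vc, A, level = 0.05, n_draws = 2e4, seed = 1)
  expect_lt(abs(thr1 - 0.05), 0.006)

  gm <- genotype_matrix(X, data.frame(marker = paste0("m", 1:30), chr = "1",
                                      bp = (1:30) * 100L), ids)
  thr30 <- chromosome_threshold(gm, vc, A, level = 0.05, n_draws = 2e4, seed = 2)
  sidak <- 1 - (1 - 0.05)^(1 / 30)
  expect_lt(abs(thr30 - sidak), 0.5 * sidak)
  expect_lt(thr30, thr1)  # multiplicity pushes the threshold down

  gd <- genotype_matrix(X[, rep(1, 10)],
                        data.frame(marker = paste0("d", 1:10), chr = "1",
                                   bp = (1:10) * 100L), ids)
  thr_dup <- chromosome_threshold(gd, vc, A, level = 0.05, n_draws = 2e4, seed = 3)
  expect_lt(abs(thr_dup - 0.05), 0.006)

  expect_error(chromosome_threshold(g1, vc, A, level = 0.001, n_draws = 500),
               "n_draws")
})

test_that("threshold sets order genome-wide below chromosome-wide", {
  # with >= 5 chromosomes the genome-wide level 0.05/n falls below the 1 %
  # chromosome-wide level, so the thresholds must order the same way
  g <- founder_genotypes(100, rep(c(0.2, 0.35, 0.3), 10), seed = 81)
  g$map$chr <- rep(as.character(1:10), each = 3)
  g$map$bp <- rep((1:3) * 1000L, 10)
  g <- genotype_matrix(g$dosage, g$map)
  A <- founder_A(rownames(g$dosage))
  vc <- structure(list(sigma2_g = 0, sigma2_e = 1, n = 100),
                  class = "variance_components")
  ts <- compute_thresholds(g, vc, A, n_draws = 3000, seed = 5)
  expect_equal(nrow(ts), 10)
  expect_true(all(ts$genome_threshold <= ts$chrom_threshold))
  # bonferroni fallback is deterministic and exact
  tb <- compute_thresholds(g, vc, A, method = "bonferroni")
  expect_equal(tb$chrom_threshold, rep(0.01 / 3, 10))
  expect_equal(tb$genome_threshold, rep(0.05 / 10 / 3, 10))
  # an unplaced-marker group gets the plain per-marker Bonferroni level
  tu <- compute_thresholds(g, vc, A, method = "bonferroni",
                           unknown_groups = "10")
  expect_equal(tu$genome_threshold[tu$chr == "10"], 0.05 / 3)
})
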