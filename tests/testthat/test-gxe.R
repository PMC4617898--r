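test_that("Fisher variance test matches the distribution-function oracle", {
  eq <- fisher_variance_test(1.4, 60, 1.4, 60)
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 1)
  eq11 <- fisher_variance_test(2, 1, 2, 1)
  expect_equal(eq11$p, 1)
  ft <- fisher_variance_test(2, 99, 1, 99)
  expect_equal(ft$F, 2)
  expect_equal(ft$p, 2 * stats::pf(2, 99, 99, lower.tail = FALSE))
  # order of arguments must not matter
  ft2 <- fisher_variance_test(1, 99, 2, 99)
  expect_equal(ft2$F, ft$F)
  expect_equal(ft2$p, ft$p)
  expect_error(fisher_variance_test(0, 10, 1, 10), "positive")
})

test_that("the literal Z statistic follows the printed formula", {
  z0 <- z_interaction(0.3, 0.3, 1, 100)
  expect_equal(z0$Z, 0)
  expect_equal(z0$p, 1)
  z4 <- z_interaction(0.2, 0, sigma2_avg = 1, n_avg = 400)
  expect_equal(z4$Z, 4)
  expect_equal(z4$p, 2 * stats::pnorm(-4))
  expect_equal(z4$p, 6.33e-5, tolerance = 1e-2)
  # scale checks: doubles with sqrt(n), shrinks with sigma
  expect_equal(z_interaction(0.2, 0, 1, 1600)$Z, 8)
  expect_equal(z_interaction(0.2, 0, 4, 400)$Z, 2)
})

test_that("the Wald variant uses the standard-error contrast", {
  zw <- z_interaction(0.5, 0.1, method = "wald", se1 = 0.1, se2 = 0.1,
                      sigma2_avg = NULL, n_avg = NULL)
  expect_equal(zw$Z, 0.4 / sqrt(0.02))
  expect_error(z_interaction(1, 0, method = "wald", se1 = NULL, se2 = 0.1,
                             sigma2_avg = NULL, n_avg = NULL))
})

test_that("interaction classes follow sign and significance", {
  expect_equal(classify_interaction(1.0, -0.5, TRUE), "sign_inversion")
  expect_equal(classify_interaction(1.0, 0.5, TRUE), "magnitude_change")
  expect_equal(classify_interaction(1.0, -0.5, FALSE), "none")
  expect_equal(classify_interaction(0, 0, TRUE), "magnitude_change")
  # antisymmetric under swapping conditions
  for (ab in list(c(1, -0.5), c(0.3, 0.8), c(-2, -1)))
    expect_equal(classify_interaction(ab[1], ab[2], TRUE),
                 classify_interaction(ab[2], ab[1], TRUE))
})

test_that("condition correlations handle trivial and degenerate input", {
  eff <- data.frame(trait = "T1",
                    condition = rep(c("HE", "LE"), each = 4),
                    marker = rep(paste0("m", 1:4), 2),
                    alpha = c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(condition_correlations(eff, "diet")$r, 1)
  eff$alpha[5:8] <- c(4, 3, 2, 1)
  expect_equal(condition_correlations(eff, "diet")$r, -1)
  few <- eff[c(1, 2, 5, 6), ]
  out <- condition_correlations(few, "diet")
  expect_true(is.na(out$r))
  expect_equal(out$n_pairs, 2)
})

test_that("independent condition effects decorrelate", {
  m <- 400
  eff <- withr::with_seed(91, data.frame(
    trait = "T1", condition = rep(c("AGE50", "AGE70"), each = m),
    marker = rep(paste0("m", seq_len(m)), 2), alpha = rnorm(2 * m)))
  r <- condition_correlations(eff, "age")$r
  expect_lt(abs(r), 3 / sqrt(m))
})

test_that("literal-Z rejection is reproducible across seed batches and power is monotone", {
  # pipeline-style use: two conditions, OLS effect estimates at one marker,
  # literal Z with the average residual variance of the condition models
  run_batch <- function(delta, n_rep, seed) {
    withr::with_seed(seed, {
      mean(replicate(n_rep, {
        n <- 200
        x <- rbinom(n, 2, 0.3)
        y1 <- (delta / 2) * x + rnorm(n)   # condition 1 (sire-mean scale)
        y2 <- rnorm(n)                      # condition 2: no effect
        f1 <- stats::lm(y1 ~ x); f2 <- stats::lm(y2 ~ x)
        s2 <- mean(c(summary(f1)$sigma^2, summary(f2)$sigma^2))
        z <- z_interaction(stats::coef(f1)[[2]], stats::coef(f2)[[2]], s2, n)
        z$p < 0.01
      }))
    })
  }
  r_a <- run_batch(0, 300, 101)
  r_b <- run_batch(0, 300, 202)
  p_pool <- (r_a + r_b) / 2
  se <- sqrt(2 * p_pool * (1 - p_pool) / 300) + 1e-3
  expect_lt(abs(r_a - r_b), 4 * se)
  power <- sapply(c(0, 0.15, 0.3, 0.6), function(d) run_batch(d, 120, 77))
  expect_true(all(diff(power) >= -0.05))
  expect_gt(power[4], power[1])
})

test_that("identical per-condition data yield zero additional QTL and Z = 0", {
  g <- founder_genotypes(60, rep(c(0.2, 0.3, 0.4), 4), seed = 111)
  A <- founder_A(rownames(g$dosage))
  z <- polygenic_means(A, 0.5, 0.5, seed = 112)
  sm_all <- data.frame(sire = names(z), condition = "ALL", mean = z,
                       n_records = 10)
  sm_cond <- rbind(
    data.frame(sire = names(z), condition = "HE", mean = z, n_records = 5),
    data.frame(sire = names(z), condition = "LE", mean = z, n_records = 5))
  res <- within_condition_scan_and_augment(sm_all, sm_cond, g, A,
                                           trait = "T1", n_draws = 1000,
                                           seed = 7)
  expect_equal(sum(res$qtls$additional), 0)
  if (!is.null(res$interactions)) {
    expect_equal(res$interactions$Z, rep(0, nrow(res$interactions)))
    expect_equal(res$interactions$class,
                 rep("none", nrow(res$interactions)))
  }
})

test_that("a planted sign-inverted QTL is recovered as an additional QTL", {
  qtl <- data.frame(marker = 12L, trait = "T1", factor = "diet",
                    alpha1 = 0.8, alpha2 = -0.8)
  cfg <- sim_config(n_sires = 200, n_daughters_per_sire = 24,
                    n_markers_per_chromosome = c("1" = 30, "2" = 30),
                    traits = data.frame(trait = "T1", type = "production",
                                        mu = 50),
                    qtl = qtl, sigma2_g = 0.3, sigma2_e = 0.5, seed = 314)
  sim <- simulate_dataset(cfg)
  rec <- sim$phenotypes[sim$phenotypes$trait == "T1", ]
  adj <- select_and_adjust(rec, model_spec("T1", "production"))
  sm_all <- sire_means(adj$records, "ALL")
  sm_diet <- sire_means(adj$records, "by-diet")
  A <- build_A(sim$pedigree)
  res <- within_condition_scan_and_augment(sm_all, sm_diet, sim$genotypes, A,
                                           trait = "T1", n_draws = 1000,
                                           seed = 8)
  planted_bp <- sim$genotypes$map$bp[12]
  hits <- res$qtls[res$qtls$chr == sim$genotypes$map$chr[12] &
                     res$qtls$ci_start <= planted_bp &
                     planted_bp <= res$qtls$ci_end, ]
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$additional))
  it <- res$interactions
  it <- it[it$factor == "diet" & it$top_marker %in% hits$top_marker, ]
  expect_true(any(it$class == "sign_inversion"))
})
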