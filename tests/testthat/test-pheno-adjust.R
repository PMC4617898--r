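# Balanced toy records: n_sires x n_rep records in one hatch, optional
# planted diet/battery effects, standard-normal residuals.
toy_records <- function(n_sires = 20, n_rep = 10, diet_effect = 0,
                        battery_effect = 0, sire_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    sires <- sprintf("s%02d", seq_len(n_sires))
    sire_eff <- stats::setNames(rnorm(n_sires, 0, sire_sd), sires)
    rec <- expand.grid(sire = sires, rep = seq_len(n_rep),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rec$diet <- ifelse(rec$rep %% 2 == 0, "HE", "LE")
    rec$battery <- paste0("B", ((rec$rep - 1) %/% 2) %% 2 + 1)
    rec$column <- "middle"; rec$floor <- "F1"; rec$hatch <- "H1"
    rec$age <- NA_character_
    rec$value <- sire_eff[rec$sire] +
      diet_effect * (rec$diet == "HE") +
      battery_effect * (rec$battery == "B2") +
      rnorm(nrow(rec))
    rec$record_id <- sprintf("r%04d", seq_len(nrow(rec)))
    rec
  })
}

test_that("a planted diet effect is estimated at the normal-equations solution", {
  rec <- toy_records(diet_effect = 2, seed = 2)
  fit <- fit_fixed_model(rec, model_spec("T1", "production"))
  expect_identical(fit$coding, "sum-to-zero")
  # independent oracle: explicit normal-equations solve on the same design
  X <- stats::model.matrix(~ sire + diet + battery, rec,
                           contrasts.arg = list(sire = "contr.sum",
                                                diet = "contr.sum",
                                                battery = "contr.sum"))
  beta <- solve(crossprod(X), crossprod(X, rec$value))
  got <- stats::coef(fit$fit)
  expect_equal(unname(got["diet1"]), unname(beta["diet1", 1]), tolerance = 1e-10)
  # sum-to-zero: diet effect difference LE - HE is -2 * diet1 coefficient
  est_diff <- -2 * got[["diet1"]]
  se2 <- 2 * sqrt(diag(solve(crossprod(X)))["diet1"])
  expect_lt(abs(est_diff - (-2)), 3 * se2)  # HE is level 1: diff = -2
  expect_lt(fit$p_values[["diet"]], 1e-6)
})

test_that("with no retained terms, adjustment subtracts the grand mean", {
  rec <- toy_records(seed = 3)
  rec$diet <- "HE"; rec$battery <- "B1"  # single-level factors drop out
  adj <- select_and_adjust(rec, model_spec("T1", "production"))
  expect_equal(adj$records$adjusted, adj$records$value - mean(rec$value),
               tolerance = 1e-12)
})

test_that("adjusted sire means match the normal-equations oracle", {
  rec <- toy_records(diet_effect = 1.5, battery_effect = 0.8, seed = 4)
  adj <- select_and_adjust(rec, model_spec("T1", "production"))
  expect_setequal(adj$models$H1$retained, c("diet", "battery"))
  # oracle: solve the same least-squares problem directly, subtract the
  # non-sire part including the intercept, and average per sire
  X <- stats::model.matrix(~ sire + diet + battery, rec,
                           contrasts.arg = list(sire = "contr.sum",
                                                diet = "contr.sum",
                                                battery = "contr.sum"))
  beta <- solve(crossprod(X), crossprod(X, rec$value))
  nonsire <- !grepl("^sire", colnames(X))
  oracle_adj <- rec$value - drop(X[, nonsire] %*% beta[nonsire, ])
  oracle_sm <- tapply(oracle_adj, rec$sire, mean)
  sm <- sire_means(adj$records, "ALL")
  expect_equal(sm$mean, as.numeric(oracle_sm[sm$sire]), tolerance = 1e-10)
})

test_that("trimming excludes strictly beyond the SD cut, once, after adjustment", {
  rec <- toy_records(n_sires = 10, n_rep = 20, seed = 5)
  rec$diet <- "HE"; rec$battery <- "B1"  # sire-only model: adjusted = centred
  # place one record at ~5 SD and one at ~3.9 SD of the post-inclusion spread
  place_at <- function(values, z_target) {
    f <- function(t) {
      v <- c(values, t)
      (t - mean(v)) / sd(v) - z_target
    }
    stats::uniroot(f, c(0, 1e4))$root
  }
  v5 <- place_at(rec$value, 5)
  v39 <- place_at(c(rec$value, v5), 3.9)
  extra <- rec[1:2, ]
  extra$record_id <- c("out5", "out39")
  extra$value <- c(v5, v39)
  rec2 <- rbind(rec, extra)
  adj <- select_and_adjust(rec2, model_spec("T1", "production"), sd_trim = 4)
  expect_true("out5" %in% adj$excluded$record_id)
  expect_false("out39" %in% adj$excluded$record_id)
  expect_true("out39" %in% adj$records$record_id)
})

test_that("sire means reduce to the record for singleton groups", {
  rec <- data.frame(sire = c("a", "b"), adjusted = c(1.5, -2),
                    diet = c("HE", "LE"), age = NA_character_)
  sm <- sire_means(rec, "ALL")
  expect_equal(sm$mean, c(1.5, -2))
  expect_equal(sm$n_records, c(1L, 1L))
})

test_that("the ALL mean is the record-weighted combination of condition means", {
  rec <- toy_records(seed = 6)
  rec$adjusted <- rec$value
  sm_all <- sire_means(rec, "ALL")
  sm_diet <- sire_means(rec, "by-diet")
  recombined <- sapply(sm_all$sire, function(s) {
    d <- sm_diet[sm_diet$sire == s, ]
    sum(d$mean * d$n_records) / sum(d$n_records)
  })
  expect_equal(sm_all$mean, unname(recombined), tolerance = 1e-12)
})

test_that("adjustment removes a planted battery effect from sire means", {
  base <- toy_records(seed = 7)
  bumped <- base
  bumped$value <- base$value + 3 * (base$battery == "B2")
  sm0 <- sire_means(select_and_adjust(base, model_spec("T1", "production"))$records, "ALL")
  sm1 <- sire_means(select_and_adjust(bumped, model_spec("T1", "production"))$records, "ALL")
  # balanced design: the bump is orthogonal to sires, so means barely move
  expect_lt(max(abs(sm0$mean - sm1$mean)), 0.02)
})

test_that("identical values across conditions give correlation one", {
  rec <- toy_records(seed = 8)
  rec$adjusted <- rec$value
  # force diets to see the same per-sire values: duplicate records per diet
  dup <- rbind(transform(rec, diet = "HE"), transform(rec, diet = "LE"))
  sm <- sire_means(dup, "by-diet")
  r <- condition_correlations(cbind(sm, trait = "T1"), "diet")$r
  expect_equal(r, 1)
})
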