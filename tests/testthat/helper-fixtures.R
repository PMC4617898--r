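# Shared fixture builders. Everything is generated in code, seeded.

# Unrelated founder sires with binomial genotypes at the given MAFs.
founder_genotypes <- function(n, mafs, seed = 1, chr = "1") {
  ids <- sprintf("s%03d", seq_len(n))
  d <- withr::with_seed(seed, {
    matrix(stats::rbinom(n * length(mafs), 2, rep(mafs, each = n)),
           n, length(mafs))
  })
  genotype_matrix(d, data.frame(marker = sprintf("m%03d", seq_along(mafs)),
                                chr = chr, bp = seq_along(mafs) * 1000L),
                  ids)
}

founder_A <- function(ids) {
  build_A(data.frame(id = ids, sire = NA_character_, dam = NA_character_))
}

# Random two-generation pedigree: nf founders, then n - nf individuals with
# parents drawn among earlier individuals (sire and dam distinct).
random_pedigree <- function(n, nf = max(4, n %/% 3), seed = 1) {
  withr::with_seed(seed, {
    id <- sprintf("i%02d", seq_len(n))
    sire <- dam <- rep(NA_character_, n)
    for (k in (nf + 1):n) {
      pick <- sample(seq_len(k - 1), 2)
      sire[k] <- id[pick[1]]
      dam[k] <- id[pick[2]]
    }
    data.frame(id = id, sire = sire, dam = dam)
  })
}

# Polygenic-only sire means: z = L'g + e with L = chol(A).
polygenic_means <- function(A, sigma2_g = 1, sigma2_e = 1, seed = 1) {
  n <- nrow(A)
  L <- chol(A + diag(1e-10, n))
  withr::with_seed(seed, {
    stats::setNames(
      drop(crossprod(L, stats::rnorm(n, 0, sqrt(sigma2_g)))) +
        stats::rnorm(n, 0, sqrt(sigma2_e)),
      rownames(A))
  })
}
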