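#' Simulation configuration for a daughter-design GWAS
#'
#' Describes the population and design to simulate: genotyped sires with a
#' half-sib pedigree structure, crossbred daughters housed in collective
#' cages of half-sisters, cages split between a high-energy (HE) and a
#' low-energy (LE) diet, egg-quality records collected at two ages (50 and
#' 70 weeks), a polygenic term with pedigree covariance, and planted QTL
#' whose allele-substitution effects may differ between conditions.
#'
#' @param n_sires number of genotyped sires.
#' @param n_daughters_per_sire daughters per sire; together with
#'   `cage_size` this determines the number of cages per sire. Cages are
#'   split as evenly as possible between the two diets.
#' @param cage_size half-sisters per collective cage (default 12).
#' @param n_markers_per_chromosome named integer vector, chromosome label to
#'   marker count.
#' @param maf_range bounds of the uniform distribution of minor allele
#'   frequencies, within (0, 0.5].
#' @param qtl data.frame of planted QTL with columns `marker` (index into
#'   the concatenated map), `trait`, `factor` (`"diet"`, `"age"` or
#'   `"none"`) and `alpha1`, `alpha2`: the allele substitution effect, in
#'   trait units per minor allele carried by the daughter, in the first
#'   condition (HE or 50 wk) and the second (LE or 70 wk). With
#'   `factor = "none"` only `alpha1` is used, in all records.
#' @param traits data.frame with columns `trait`, `type` (`"production"` for
#'   cage-level records without an age dimension, `"quality"` for egg-level
#'   records at both ages) and `mu` (trait mean).
#' @param sigma2_g additive polygenic variance among sire breeding values.
#' @param sigma2_e residual variance of one record.
#' @param n_sires_per_grandsire half-sib family size in the sire pedigree;
#'   grandsires are ungenotyped founders.
#' @param n_hatches number of hatches; cages are nested within hatch.
#' @param fixed_effect_sd named list of standard deviations used to draw the
#'   fixed-effect level values: `diet`, `age`, `battery`, `column`, `floor`,
#'   `operator`, and covariate slopes `beta_w` (waiting time, days) and
#'   `beta_r` (hen age, days). Zero switches an effect off.
#' @param seed integer seed; the whole dataset is a pure function of the
#'   configuration including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 300,
                       n_daughters_per_sire = 24,
                       cage_size = 12,
                       n_markers_per_chromosome = c("1" = 50, "2" = 50, "3" = 50, "4" = 50),
                       maf_range = c(0.1, 0.5),
                       qtl = NULL,
                       traits = data.frame(trait = c("EPR1", "ESC"),
                                           type = c("production", "quality"),
                                           mu = c(75, 25)),
                       sigma2_g = 1,
                       sigma2_e = 1,
                       n_sires_per_grandsire = 10,
                       n_hatches = 2,
                       fixed_effect_sd = list(diet = 0.5, age = 0.5, battery = 0.3,
                                              column = 0.2, floor = 0.2, operator = 0.3,
                                              beta_w = 0.02, beta_r = 0.005),
                       seed = 1L) {
  stopifnot(
    n_sires >= 1, n_daughters_per_sire >= 1, cage_size >= 1,
    sigma2_g >= 0, sigma2_e >= 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    all(n_markers_per_chromosome >= 1),
    all(traits$type %in% c("production", "quality"))
  )
  m_total <- sum(n_markers_per_chromosome)
  if (!is.null(qtl)) {
    stopifnot(all(c("marker", "trait", "factor", "alpha1", "alpha2") %in% names(qtl)))
    if (any(qtl$marker < 1 | qtl$marker > m_total))
      stop("qtl marker index outside the simulated map")
    if (!all(qtl$trait %in% traits$trait))
      stop("qtl references a trait not in the trait list: ",
           paste(setdiff(qtl$trait, traits$trait), collapse = ", "))
    if (!all(qtl$factor %in% c("diet", "age", "none")))
      stop("qtl factor must be 'diet', 'age' or 'none'")
    prod_traits <- traits$trait[traits$type == "production"]
    if (any(qtl$factor == "age" & qtl$trait %in% prod_traits))
      stop("age-dependent QTL cannot act on production traits (no age dimension)")
  }
  structure(list(
    n_sires = n_sires, n_daughters_per_sire = n_daughters_per_sire,
    cage_size = cage_size, n_markers_per_chromosome = n_markers_per_chromosome,
    maf_range = maf_range, qtl = qtl, traits = traits,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    n_sires_per_grandsire = n_sires_per_grandsire, n_hatches = n_hatches,
    fixed_effect_sd = fixed_effect_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a daughter-design dataset
#'
#' Generates a sire pedigree (paternal half-sib families under ungenotyped
#' grandsire founders), sire genotypes at the configured marker density,
#' and daughter phenotype records. Each daughter's record is
#' `mu + fixed effects + covariate terms + 0.5 * sire breeding value +
#' Mendelian-sampling deviation + planted-QTL contribution + residual`.
#' Daughters inherit one sire allele at each QTL with probability
#' `dosage/2` and one allele from an unrelated dam pool at the simulated
#' allele frequency; only sires are genotyped, so the output genotypes
#' cover sires alone.
#'
#' @param config a [sim_config()].
#' @return list with elements `pedigree` (data.frame `id`, `sire`, `dam`;
#'   `NA` for unknown parents), `genotypes` (a [genotype_matrix()] over
#'   sires), `phenotypes` (long data.frame of records: `record_id`, `sire`,
#'   `hatch`, `diet`, `age`, `battery`, `column`, `floor`, `operator`, `W`,
#'   `R`, `trait`, `value`), and `truth` (breeding values, level effects and
#'   the planted QTL, for validation).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed, 6)
  n_s <- config$n_sires

  ## pedigree: grandsire founders, sires in half-sib families, dams unknown
  n_gs <- max(1L, ceiling(n_s / config$n_sires_per_grandsire))
  gs_ids <- sprintf("GS%03d", seq_len(n_gs))
  sire_ids <- sprintf("S%04d", seq_len(n_s))
  ped <- rbind(
    data.frame(id = gs_ids, sire = NA_character_, dam = NA_character_),
    data.frame(id = sire_ids,
               sire = gs_ids[((seq_len(n_s) - 1L) %% n_gs) + 1L],
               dam = NA_character_)
  )

  ## marker map and sire genotypes at HWE
  counts <- config$n_markers_per_chromosome
  # positions: deterministic 100 kb ladder, strictly increasing per chromosome
  map <- data.frame(
    marker = sprintf("AX-%05d", seq_len(sum(counts))),
    chr = rep(names(counts), counts),
    bp = unlist(lapply(counts, function(k) seq(100000L, by = 100000L, length.out = k)),
                use.names = FALSE)
  )
  mafs <- with_seed(seeds[1],
                    stats::runif(sum(counts), config$maf_range[1], config$maf_range[2]))
  dosage <- with_seed(seeds[2], {
    matrix(stats::rbinom(n_s * sum(counts), 2L, rep(mafs, each = n_s)),
           nrow = n_s, ncol = sum(counts))
  })
  geno <- genotype_matrix(dosage, map, sire_ids)

  ## breeding values over the pedigree: founders N(0, sg2), offspring
  ## 0.5 * sire + Mendelian sampling (dams unknown -> unrelated pool)
  sg2 <- config$sigma2_g
  u <- with_seed(seeds[3], {
    u_gs <- stats::rnorm(n_gs, 0, sqrt(sg2))
    names(u_gs) <- gs_ids
    ms <- stats::rnorm(n_s, 0, sqrt(0.75 * sg2))
    u_s <- 0.5 * u_gs[ped$sire[match(sire_ids, ped$id)]] + ms
    names(u_s) <- sire_ids
    c(u_gs, u_s)
  })

  ## design: cages of half-sisters, split across diets, nested in hatches
  cages_per_sire <- ceiling(config$n_daughters_per_sire / config$cage_size)
  cage_tab <- expand.grid(sire = sire_ids, cage_rep = seq_len(cages_per_sire),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cage_tab$cage_id <- sprintf("C%05d", seq_len(nrow(cage_tab)))
  cage_tab$diet <- ifelse(cage_tab$cage_rep %% 2L == 1L, "HE", "LE")
  n_cages <- nrow(cage_tab)
  fx <- config$fixed_effect_sd
  lev <- with_seed(seeds[4], list(
    diet = stats::setNames(stats::rnorm(2, 0, fx$diet %||% 0), c("HE", "LE")),
    age = stats::setNames(stats::rnorm(2, 0, fx$age %||% 0), c("50", "70")),
    battery = stats::setNames(stats::rnorm(4, 0, fx$battery %||% 0), paste0("B", 1:4)),
    column = stats::setNames(stats::rnorm(2, 0, fx$column %||% 0), c("middle", "edge")),
    floor = stats::setNames(stats::rnorm(2, 0, fx$floor %||% 0), c("F1", "F2")),
    operator = stats::setNames(stats::rnorm(8, 0, fx$operator %||% 0), paste0("OP", 1:8))
  ))
  cage_env <- with_seed(seeds[5], data.frame(
    battery = sample(names(lev$battery), n_cages, replace = TRUE),
    column = sample(names(lev$column), n_cages, replace = TRUE),
    floor = sample(names(lev$floor), n_cages, replace = TRUE),
    hatch = paste0("H", sample.int(config$n_hatches, n_cages, replace = TRUE))
  ))
  cage_tab <- cbind(cage_tab, cage_env)

  ## daughters: sire allele transmitted with probability dosage/2 at each
  ## planted QTL; dam allele drawn from the population at the marker's MAF
  qtl <- config$qtl
  phen <- with_seed(seeds[6], {
    out <- list()
    for (ti in seq_len(nrow(config$traits))) {
      tr <- config$traits$trait[ti]
      type <- config$traits$type[ti]
      mu <- config$traits$mu[ti]
      qt <- if (is.null(qtl)) NULL else qtl[qtl$trait == tr, , drop = FALSE]
      # per-daughter genetic values, daughters indexed within cages
      n_daughters <- n_cages * config$cage_size
      cage_of <- rep(seq_len(n_cages), each = config$cage_size)
      sire_of <- cage_tab$sire[cage_of]
      sire_idx <- match(sire_of, sire_ids)
      g_poly <- 0.5 * u[sire_of] +
        stats::rnorm(n_daughters, 0, sqrt(0.75 * sg2))
      # QTL dosage of each daughter at each planted marker (fixed across ages)
      qd <- NULL
      if (!is.null(qt) && nrow(qt)) {
        qd <- sapply(seq_len(nrow(qt)), function(k) {
          j <- qt$marker[k]
          sire_dos <- geno$dosage[, j][sire_idx]
          transmitted <- stats::rbinom(n_daughters, 1L, sire_dos / 2)
          dam <- stats::rbinom(n_daughters, 1L, mafs[j])
          transmitted + dam
        })
        qd <- matrix(qd, nrow = n_daughters)
      }
      qtl_contrib <- function(diet, age) {
        if (is.null(qd)) return(0)
        contrib <- numeric(n_daughters)
        for (k in seq_len(nrow(qt))) {
          a <- switch(qt$factor[k],
                      none = qt$alpha1[k],
                      diet = if (diet == "HE") qt$alpha1[k] else qt$alpha2[k],
                      age = if (age == "50") qt$alpha1[k] else qt$alpha2[k])
          contrib <- contrib + a * qd[, k]
        }
        contrib
      }
      if (type == "production") {
        # one record per cage: cage mean of daughter genetic values + fixed;
        # diet-dependent QTL contributions follow each cage's own diet
        g_cage <- tapply(g_poly, cage_of, mean)
        qv <- numeric(n_cages)
        if (!is.null(qd)) {
          per_d_he <- qtl_contrib("HE", NA)
          per_d_le <- qtl_contrib("LE", NA)
          qv <- ifelse(cage_tab$diet == "HE",
                       tapply(per_d_he, cage_of, mean),
                       tapply(per_d_le, cage_of, mean))
        }
        val <- mu + lev$diet[cage_tab$diet] + lev$battery[cage_tab$battery] +
          lev$column[cage_tab$column] + lev$floor[cage_tab$floor] +
          as.numeric(g_cage) + qv +
          stats::rnorm(n_cages, 0, sqrt(config$sigma2_e))
        out[[length(out) + 1L]] <- data.frame(
          record_id = cage_tab$cage_id, sire = cage_tab$sire,
          hatch = cage_tab$hatch, diet = cage_tab$diet, age = NA_character_,
          battery = cage_tab$battery, column = cage_tab$column,
          floor = cage_tab$floor, operator = NA_character_,
          W = NA_real_, R = NA_real_, trait = tr, value = unname(val)
        )
      } else {
        # one egg record per daughter per age
        for (age in c("50", "70")) {
          op <- sample(names(lev$operator), n_daughters, replace = TRUE)
          W <- stats::runif(n_daughters, 1, 10)           # waiting time, days
          R <- (as.numeric(age) * 7) + stats::runif(n_daughters, -10, 10)
          val <- mu + lev$diet[cage_tab$diet[cage_of]] + lev$age[age] +
            lev$battery[cage_tab$battery[cage_of]] +
            lev$column[cage_tab$column[cage_of]] +
            lev$floor[cage_tab$floor[cage_of]] + lev$operator[op] +
            (fx$beta_w %||% 0) * (W - mean(W)) +
            (fx$beta_r %||% 0) * (R - mean(R)) +
            g_poly + qtl_contrib(cage_tab$diet[cage_of], age) +
            stats::rnorm(n_daughters, 0, sqrt(config$sigma2_e))
          out[[length(out) + 1L]] <- data.frame(
            record_id = sprintf("%s-D%02d-A%s", cage_tab$cage_id[cage_of],
                                (seq_len(n_daughters) - 1L) %% config$cage_size + 1L, age),
            sire = sire_of, hatch = cage_tab$hatch[cage_of],
            diet = cage_tab$diet[cage_of], age = age,
            battery = cage_tab$battery[cage_of],
            column = cage_tab$column[cage_of],
            floor = cage_tab$floor[cage_of], operator = op,
            W = W, R = R, trait = tr, value = unname(val)
          )
        }
      }
    }
    do.call(rbind, out)
  })
  rownames(phen) <- NULL

  list(pedigree = ped, genotypes = geno, phenotypes = phen,
       truth = list(breeding_values = u, level_effects = lev,
                    mafs = mafs, qtl = qtl, config = config))
}
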