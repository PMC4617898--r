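#' Fisher test for equality of two residual variances
#'
#' Two-sided variance-ratio test: `F` is the larger variance over the
#' smaller, and the p-value is twice the upper-tail F probability, capped
#' at 1.
#'
#' @param s1_sq,s2_sq residual variances (positive).
#' @param df1,df2 their degrees of freedom.
#' @return list `F`, `p`, `df` (numerator, denominator).
#' @export
fisher_variance_test <- function(s1_sq, df1, s2_sq, df2) {
  if (s1_sq <= 0 || s2_sq <= 0) stop("variances must be positive")
  stopifnot(df1 >= 1, df2 >= 1)
  if (s1_sq >= s2_sq) {
    F <- s1_sq / s2_sq; dfn <- df1; dfd <- df2
  } else {
    F <- s2_sq / s1_sq; dfn <- df2; dfd <- df1
  }
  p <- min(1, 2 * stats::pf(F, dfn, dfd, lower.tail = FALSE))
  list(F = F, p = p, df = c(dfn, dfd))
}

#' Z test for a QTL-by-environment interaction
#'
#' Compares the allele substitution effects estimated in two conditions.
#' The `"literal"` statistic is `Z = |alpha1 - alpha2| / sigma * sqrt(n)`,
#' where `sigma^2` is the average residual variance and `n` the average
#' number of sires over the two conditions; Z is referred to the standard
#' normal (two-sided). The `"wald"` variant is the variance-correct
#' contrast `|alpha1 - alpha2| / sqrt(se1^2 + se2^2)`, available for
#' calibration studies; the literal statistic ignores the genotype-variance
#' scaling and the factor sqrt(2) of a difference of two estimates, so its
#' operating characteristics differ from a nominal normal test.
#'
#' @param alpha1,alpha2 per-condition allele substitution effects.
#' @param sigma2_avg average residual variance over the two conditions
#'   (from the within-condition null mixed models).
#' @param n_avg average number of sires over the two conditions.
#' @param method `"literal"` (default) or `"wald"`.
#' @param se1,se2 per-condition standard errors (wald variant only).
#' @return list `Z`, `p` (two-sided), `method`.
#' @examples
#' z_interaction(0.2, 0, sigma2_avg = 1, n_avg = 400) # Z = 4
#' @export
z_interaction <- function(alpha1, alpha2, sigma2_avg, n_avg,
                          method = c("literal", "wald"),
                          se1 = NULL, se2 = NULL) {
  method <- match.arg(method)
  if (method == "literal") {
    stopifnot(sigma2_avg > 0, n_avg >= 2)
    Z <- abs(alpha1 - alpha2) / sqrt(sigma2_avg) * sqrt(n_avg)
  } else {
    stopifnot(!is.null(se1), !is.null(se2), se1 > 0, se2 > 0)
    Z <- abs(alpha1 - alpha2) / sqrt(se1^2 + se2^2)
  }
  list(Z = Z, p = 2 * stats::pnorm(-Z), method = method)
}

# Significance stars at the reporting levels 0.1 / 0.05 / 0.01.
significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Classify a significant interaction
#'
#' A significant interaction is a `"sign_inversion"` when the two
#' per-condition effects have opposite signs (at least one non-zero), and a
#' `"magnitude_change"` otherwise; non-significant interactions are
#' `"none"`.
#'
#' @param alpha1,alpha2 per-condition effects.
#' @param significant logical.
#' @return one of `"sign_inversion"`, `"magnitude_change"`, `"none"`.
#' @export
classify_interaction <- function(alpha1, alpha2, significant) {
  if (!significant) return("none")
  if (sign(alpha1) != sign(alpha2) && (alpha1 != 0 || alpha2 != 0))
    "sign_inversion"
  else "magnitude_change"
}

#' Correlations between conditions
#'
#' Pearson correlation, per trait, of paired sire means (phenotypic level)
#' or paired SNP effects (genetic level) between the two members of a
#' condition pair: HE vs LE diets or the 50 vs 70 week ages.
#'
#' @param x data.frame with columns `trait` (optional), `condition`, a key
#'   column (`sire` or `marker`) and a value column (`mean` or `alpha`).
#' @param pairing `"diet"` or `"age"`.
#' @return data.frame `trait`, `r`, `n_pairs`; `r` is `NA` (flagged) with
#'   fewer than 3 complete pairs.
#' @export
condition_correlations <- function(x, pairing = c("diet", "age")) {
  pairing <- match.arg(pairing)
  conds <- if (pairing == "diet") c("HE", "LE") else c("AGE50", "AGE70")
  key <- if ("sire" %in% names(x)) "sire" else "marker"
  val <- if ("mean" %in% names(x)) "mean" else "alpha"
  if (!"trait" %in% names(x)) x$trait <- "trait"
  out <- lapply(unique(x$trait), function(tr) {
    xi <- x[x$trait == tr, , drop = FALSE]
    a <- xi[xi$condition == conds[1], c(key, val)]
    b <- xi[xi$condition == conds[2], c(key, val)]
    mm <- merge(a, b, by = key)
    mm <- mm[stats::complete.cases(mm), , drop = FALSE]
    r <- if (nrow(mm) < 3) NA_real_ else stats::cor(mm[[2]], mm[[3]])
    data.frame(trait = tr, r = r, n_pairs = nrow(mm))
  })
  do.call(rbind, out)
}

#' Within-condition scans, additional QTL, and interaction tests
#'
#' Runs the full per-condition analysis for one trait: for each condition
#' (two diets and, for quality traits, two ages) a null REML fit, a marker
#' scan and QTL calling; QTL found in a condition whose catalogue interval
#' does not overlap any whole-data QTL on the same chromosome are flagged
#' *additional*. Every QTL -- whole-data and additional -- then receives an
#' interaction test per factor, comparing the two per-condition effects at
#' its top SNP with the Z statistic (and the residual variances with the
#' Fisher test).
#'
#' @param sm_all [sire_means()] for the whole data (condition `ALL`).
#' @param sm_cond per-condition sire means: a data.frame covering
#'   conditions among `HE`, `LE`, `AGE50`, `AGE70`.
#' @param g a [genotype_matrix()] (post-QC).
#' @param A relationship matrix over the sires.
#' @param trait trait name carried through to outputs.
#' @param chrom_level,genome_alpha,n_chromosomes,threshold_method,n_draws
#'   passed to [compute_thresholds()].
#' @param gap_tolerance passed to [call_qtls()].
#' @param z_method `"literal"` or `"wald"` (see [z_interaction()]).
#' @param star_level significance level used for classification (default
#'   0.1, the loosest reporting level).
#' @param seed RNG seed for the Monte-Carlo thresholds.
#' @return list with `qtls` (whole-data QTL with an `additional = FALSE`
#'   flag, plus per-condition additional QTL with `additional = TRUE` and
#'   their `condition`), `interactions` (one row per QTL x factor:
#'   `alpha1`, `alpha2`, `sigma2_avg`, `n_avg`, `fisher_F`, `fisher_p`,
#'   `Z`, `p`, `stars`, `class`), `scans` (per-condition `assoc_result`s)
#'   and `vc` (per-condition variance components).
#' @export
within_condition_scan_and_augment <- function(sm_all, sm_cond, g, A,
                                              trait = "trait",
                                              chrom_level = 0.01,
                                              genome_alpha = 0.05,
                                              n_chromosomes = NULL,
                                              threshold_method = "montecarlo",
                                              n_draws = 2000,
                                              gap_tolerance = 0,
                                              z_method = "literal",
                                              star_level = 0.1,
                                              seed = 1) {
  conds <- intersect(c("ALL", "HE", "LE", "AGE50", "AGE70"),
                     unique(c(sm_all$condition, sm_cond$condition)))
  sm <- rbind(sm_all, sm_cond)
  seeds <- split_seed(seed, length(conds))
  names(seeds) <- conds

  ids_all <- sort(unique(sm$sire))
  eig <- eigen(A[ids_all, ids_all], symmetric = TRUE)

  vc <- list(); scans <- list(); qtl_by_cond <- list(); var_sire <- list()
  for (cond in conds) {
    smc <- sm[sm$condition == cond, , drop = FALSE]
    z <- stats::setNames(smc$mean, smc$sire)
    e <- if (identical(names(z), ids_all)) eig else NULL
    vc[[cond]] <- fit_null_reml(z, A, eig = e)
    scans[[cond]] <- scan_snps(z, g, A, vc[[cond]])
    scans[[cond]]$trait <- trait
    scans[[cond]]$condition <- cond
    var_sire[[cond]] <- stats::var(z)
    thr <- compute_thresholds(g, vc[[cond]], A, ids = names(z),
                              chrom_level = chrom_level,
                              genome_alpha = genome_alpha,
                              n_chromosomes = n_chromosomes,
                              method = threshold_method,
                              n_draws = n_draws, seed = seeds[[cond]])
    q <- call_qtls(scans[[cond]], thr, gap_tolerance = gap_tolerance,
                   var_sire = var_sire[[cond]])
    q$trait <- rep(trait, nrow(q))
    q$condition <- rep(cond, nrow(q))
    qtl_by_cond[[cond]] <- q
  }

  whole <- qtl_by_cond[["ALL"]]
  if (is.null(whole)) stop("whole-data sire means (condition ALL) are required")
  whole$additional <- rep(FALSE, nrow(whole))
  extra <- list()
  for (cond in setdiff(conds, "ALL")) {
    q <- qtl_by_cond[[cond]]
    if (!nrow(q)) next
    overlaps_whole <- vapply(seq_len(nrow(q)), function(i) {
      any(whole$chr == q$chr[i] &
            whole$ci_start <= q$ci_end[i] & q$ci_start[i] <= whole$ci_end)
    }, logical(1))
    q <- q[!overlaps_whole, , drop = FALSE]
    if (nrow(q)) {
      q$additional <- TRUE
      extra[[cond]] <- q
    }
  }
  # de-duplicate additional QTL found in both members of a pair
  qtls <- whole
  if (length(extra)) {
    ex <- do.call(rbind, extra)
    drop <- logical(nrow(ex))
    if (nrow(ex) > 1) for (i in 2:nrow(ex)) {
      drop[i] <- any(ex$chr[seq_len(i - 1)] == ex$chr[i] &
                       ex$ci_start[seq_len(i - 1)] <= ex$ci_end[i] &
                       ex$ci_start[i] <= ex$ci_end[seq_len(i - 1)] &
                       !drop[seq_len(i - 1)])
    }
    qtls <- rbind(qtls, ex[!drop, , drop = FALSE])
  }

  ## interaction tests per QTL x factor
  pairs <- list(diet = c("HE", "LE"), age = c("AGE50", "AGE70"))
  inter <- list()
  if (nrow(qtls)) for (i in seq_len(nrow(qtls))) {
    for (fac in names(pairs)) {
      c1 <- pairs[[fac]][1]; c2 <- pairs[[fac]][2]
      if (!(c1 %in% conds && c2 %in% conds)) next
      s1 <- scans[[c1]]; s2 <- scans[[c2]]
      j1 <- match(qtls$top_marker[i], s1$marker)
      j2 <- match(qtls$top_marker[i], s2$marker)
      a1 <- s1$alpha[j1]; a2 <- s2$alpha[j2]
      if (is.na(a1) || is.na(a2)) next
      s2avg <- mean(c(vc[[c1]]$sigma2_e, vc[[c2]]$sigma2_e))
      navg <- mean(c(vc[[c1]]$n, vc[[c2]]$n))
      ft <- fisher_variance_test(vc[[c1]]$sigma2_e, vc[[c1]]$n - 1,
                                 vc[[c2]]$sigma2_e, vc[[c2]]$n - 1)
      zt <- z_interaction(a1, a2, s2avg, navg, method = z_method,
                          se1 = s1$se[j1], se2 = s2$se[j2])
      pv1 <- variance_explained(s1$maf[j1], a1, var_sire[[c1]])
      pv2 <- variance_explained(s2$maf[j2], a2, var_sire[[c2]])
      inter[[length(inter) + 1L]] <- data.frame(
        trait = trait, chr = qtls$chr[i], top_marker = qtls$top_marker[i],
        additional = qtls$additional[i], factor = fac,
        alpha1 = a1, alpha2 = a2, pct_var1 = pv1, pct_var2 = pv2,
        sigma2_avg = s2avg, n_avg = navg,
        fisher_F = ft$F, fisher_p = ft$p,
        Z = zt$Z, p = zt$p, stars = significance_stars(zt$p),
        class = classify_interaction(a1, a2, zt$p < star_level))
    }
  }
  list(qtls = qtls,
       interactions = if (length(inter)) do.call(rbind, inter) else NULL,
       scans = scans, vc = vc)
}
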