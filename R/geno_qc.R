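#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation at the observed allele frequency.
#' Monomorphic markers return a statistic of 0 with p = 1 (no departure can
#' be expressed).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors are accepted and tested
#'   element-wise).
#' @return data.frame with columns `statistic` and `p_value`.
#' @examples
#' hwe_chi2(25, 50, 25) # exact HWE proportions: statistic 0, p 1
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("at least one genotype observation is required")
  p <- (2 * n_aa + n_Aa) / (2 * n)  # frequency of the 'a' allele
  eAA <- (1 - p)^2 * n
  eAa <- 2 * p * (1 - p) * n
  eaa <- p^2 * n
  stat <- numeric(length(n))
  poly <- p > 0 & p < 1
  stat[poly] <- (n_AA[poly] - eAA[poly])^2 / eAA[poly] +
    (n_Aa[poly] - eAa[poly])^2 / eAa[poly] +
    (n_aa[poly] - eaa[poly])^2 / eaa[poly]
  data.frame(statistic = stat,
             p_value = ifelse(poly, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1))
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test of Hardy-Weinberg proportions: the p-value is the
#' summed probability of all heterozygote counts (given the observed allele
#' counts) no more probable than the observed one. Preferable to the
#' chi-square for rare alleles or small samples; the chi-square remains the
#' default filter because typical sire panels have hundreds of individuals.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorised).
#' @return numeric vector of p-values.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n < 1) stop("at least one genotype observation is required")
    n_a <- 2 * bb + ab            # rarer-or-not allele count, folded below
    if (n_a > n) n_a <- 2 * n - n_a
    if (n_a == 0) return(1)
    # heterozygote counts compatible with n_a copies of the minor allele
    hets <- seq(n_a %% 2, n_a, by = 2)
    # unnormalized probabilities via the standard recurrence
    lp <- numeric(length(hets))
    for (k in seq_along(hets)[-1]) {
      h <- hets[k]
      lp[k] <- lp[k - 1] +
        log(n_a - h + 2) + log(2 * n - n_a - h + 2) -
        log(h) - log(h - 1)
    }
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- match(ab, hets)
    if (is.na(obs)) stop("inconsistent genotype counts")
    min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
  }, n_AA, n_Aa, n_aa)
}

# Fraction of non-missing calls per marker / per individual.
call_rate_markers <- function(dosage) colMeans(!is.na(dosage))
call_rate_individuals <- function(dosage) rowMeans(!is.na(dosage))

#' Sequential SNP quality-control filters
#'
#' Applies five filters strictly in order, each computed on the data
#' surviving the previous steps: (1) markers with call rate below
#' `w_call_rate_min` (catches near-null assays such as W-chromosome probes
#' typed in males); (2) individuals with call rate below
#' `ind_call_rate_min`; (3) markers with minor allele frequency below
#' `maf_min` (MAF from non-missing dosages, folded); (4) markers with call
#' rate below `snp_call_rate_min`; (5) markers deviating from
#' Hardy-Weinberg equilibrium at `hwe_alpha` by the 1-df chi-square test.
#'
#' @param g a [genotype_matrix()].
#' @param snp_call_rate_min,ind_call_rate_min,maf_min,hwe_alpha,w_call_rate_min
#'   thresholds; a marker/individual is excluded when its statistic is
#'   strictly below the call-rate/MAF threshold, or its HWE p-value strictly
#'   below `hwe_alpha`.
#' @param hwe_test `"chisq"` (default, [hwe_chi2()]) or `"exact"`
#'   ([hwe_exact()]).
#' @return list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a `filter_report`).
#' @export
apply_snp_filters <- function(g, snp_call_rate_min = 0.95,
                              ind_call_rate_min = 0.95,
                              maf_min = 0.05, hwe_alpha = 0.05,
                              w_call_rate_min = 0.05,
                              hwe_test = c("chisq", "exact")) {
  hwe_test <- match.arg(hwe_test)
  stopifnot(inherits(g, "genotype_matrix"))
  n_m0 <- ncol(g$dosage)
  n_i0 <- nrow(g$dosage)
  steps <- list()
  note_step <- function(name, criterion, threshold, m_excl, i_excl) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, criterion = criterion, threshold = threshold,
      n_markers_excluded = m_excl, n_individuals_excluded = i_excl)
  }
  check_nonempty <- function(g, report) {
    if (ncol(g$dosage) == 0L || nrow(g$dosage) == 0L)
      stop(errorCondition(
        "no markers or individuals survive the filter sequence",
        report = report, class = c("eggqtl_empty_filter_error", "error")))
  }

  # (1) near-null marker call rate
  drop1 <- call_rate_markers(g$dosage) < w_call_rate_min
  g <- subset_genotypes(g, markers = which(!drop1))
  note_step("marker_call_rate_low", "marker call rate <", w_call_rate_min,
            sum(drop1), 0L)
  # (2) individual call rate
  drop2 <- call_rate_individuals(g$dosage) < ind_call_rate_min
  g <- subset_genotypes(g, sires = which(!drop2))
  note_step("individual_call_rate", "individual call rate <",
            ind_call_rate_min, 0L, sum(drop2))
  check_nonempty(g, build_filter_report(steps, n_m0, n_i0))
  # (3) minor allele frequency
  # untyped markers have no defined MAF; they fall to the call-rate steps
  maf <- marker_maf(g)
  drop3 <- !is.na(maf) & maf < maf_min
  g <- subset_genotypes(g, markers = which(!drop3))
  note_step("maf", "MAF <", maf_min, sum(drop3), 0L)
  # (4) marker call rate
  drop4 <- call_rate_markers(g$dosage) < snp_call_rate_min
  g <- subset_genotypes(g, markers = which(!drop4))
  note_step("marker_call_rate", "marker call rate <", snp_call_rate_min,
            sum(drop4), 0L)
  # (5) Hardy-Weinberg
  nAA <- colSums(g$dosage == 0, na.rm = TRUE)
  nAa <- colSums(g$dosage == 1, na.rm = TRUE)
  naa <- colSums(g$dosage == 2, na.rm = TRUE)
  typed <- nAA + nAa + naa >= 1   # untyped markers cannot show HWE departure
  hwe_p <- rep(1, ncol(g$dosage))
  if (any(typed))
    hwe_p[typed] <- if (hwe_test == "chisq")
      hwe_chi2(nAA[typed], nAa[typed], naa[typed])$p_value
    else hwe_exact(nAA[typed], nAa[typed], naa[typed])
  drop5 <- hwe_p < hwe_alpha
  g <- subset_genotypes(g, markers = which(!drop5))
  note_step("hwe", "HWE chi-square p <", hwe_alpha, sum(drop5), 0L)

  report <- build_filter_report(steps, n_m0, n_i0)
  check_nonempty(g, report)
  list(genotypes = g, report = report)
}

# Assemble a filter_report from per-step rows plus initial counts.
build_filter_report <- function(steps, n_markers_initial, n_individuals_initial) {
  tab <- do.call(rbind, steps)
  filter_report(tab, n_markers_initial, n_individuals_initial)
}

#' Filter report
#'
#' Ledger of a sequential QC run: one row per executed step with the
#' criterion, threshold and exclusion counts, plus initial counts. Final
#' counts are derived by subtraction and must reconcile.
#'
#' @param steps data.frame with columns `step`, `criterion`, `threshold`,
#'   `n_markers_excluded`, `n_individuals_excluded`, in executed order.
#' @param n_markers_initial,n_individuals_initial counts before step 1.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(steps, n_markers_initial, n_individuals_initial) {
  stopifnot(all(c("step", "n_markers_excluded", "n_individuals_excluded")
                %in% names(steps)),
            all(steps$n_markers_excluded >= 0),
            all(steps$n_individuals_excluded >= 0))
  structure(list(
    steps = steps,
    n_markers_initial = n_markers_initial,
    n_individuals_initial = n_individuals_initial,
    n_markers_final = n_markers_initial - sum(steps$n_markers_excluded),
    n_individuals_final = n_individuals_initial - sum(steps$n_individuals_excluded)
  ), class = "filter_report")
}

#' Reconcile a filter report
#'
#' Checks that initial counts minus the per-step exclusions equal the final
#' counts, for markers and individuals separately.
#'
#' @param report a [filter_report()].
#' @return invisibly `TRUE`; errors if the ledger does not reconcile.
#' @export
reconcile_filter_report <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  m_ok <- report$n_markers_initial - sum(report$steps$n_markers_excluded) ==
    report$n_markers_final
  i_ok <- report$n_individuals_initial - sum(report$steps$n_individuals_excluded) ==
    report$n_individuals_final
  if (!m_ok || !i_ok) stop("filter ledger does not reconcile")
  invisible(TRUE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter ledger:", x$n_markers_initial, "markers,",
      x$n_individuals_initial, "individuals in\n")
  print(x$steps, row.names = FALSE)
  cat("retained:", x$n_markers_final, "markers,",
      x$n_individuals_final, "individuals\n")
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) x$steps
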