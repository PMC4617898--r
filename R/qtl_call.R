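#' Call QTL from a marker scan
#'
#' Per chromosome, every maximal run of consecutive chromosome-wide
#' significant markers (runs broken by more than `gap_tolerance`
#' consecutive non-significant markers) that contains at least one
#' genome-wide significant marker becomes one QTL. The confidence interval
#' is the closed bp interval from the first to the last marker of the run,
#' and the top SNP is the run's marker with the largest `|alpha|`.
#'
#' @param results an `assoc_result` data.frame from [scan_snps()].
#' @param thresholds a `threshold_set` from [compute_thresholds()].
#' @param gap_tolerance number of consecutive non-significant markers
#'   allowed inside a run (default 0).
#' @param var_sire variance of the sire means that were scanned; when
#'   given, `pct_var` (variance explained by the top SNP,
#'   `100 * 2p(1-p)alpha^2 / var_sire`) is filled in.
#' @return data.frame of class `qtl_record`: `chr`, `ci_start`, `ci_end`,
#'   `top_marker`, `top_bp`, `alpha`, `se`, `p`, `maf`, `n_markers`,
#'   `pct_var`. Zero rows when nothing is genome-wide significant.
#' @export
call_qtls <- function(results, thresholds, gap_tolerance = 0, var_sire = NULL) {
  out <- list()
  for (cc in unique(results$chr)) {
    res <- results[results$chr == cc, , drop = FALSE]
    res <- res[order(res$bp), , drop = FALSE]
    thr <- thresholds[thresholds$chr == cc, , drop = FALSE]
    if (nrow(thr) != 1) next
    sig_g <- !is.na(res$p) & res$p < thr$genome_threshold
    # genome-wide significance implies chromosome-wide membership even if
    # Monte-Carlo noise (or a small chromosome count) orders the two
    # thresholds the other way round
    sig_c <- (!is.na(res$p) & res$p < thr$chrom_threshold) | sig_g
    if (!any(sig_g)) next
    # runs of chromosome-wide significant markers, allowing gaps
    run_id <- integer(nrow(res))
    current <- 0L
    gap <- Inf
    for (i in seq_len(nrow(res))) {
      if (sig_c[i]) {
        if (gap > gap_tolerance) current <- current + 1L
        run_id[i] <- current
        gap <- 0
      } else {
        gap <- gap + 1
      }
    }
    for (r in seq_len(max(run_id))) {
      jj <- which(run_id == r)
      if (!any(sig_g[jj])) next
      top <- jj[which.max(abs(res$alpha[jj]))]
      pv <- if (!is.null(var_sire))
        variance_explained(res$maf[top], res$alpha[top], var_sire)
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chr = cc, ci_start = res$bp[jj[1]], ci_end = res$bp[jj[length(jj)]],
        top_marker = res$marker[top], top_bp = res$bp[top],
        alpha = res$alpha[top], se = res$se[top], p = res$p[top],
        maf = res$maf[top], n_markers = length(jj), pct_var = pv)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(chr = character(0), ci_start = numeric(0),
                  ci_end = numeric(0), top_marker = character(0),
                  top_bp = numeric(0), alpha = numeric(0), se = numeric(0),
                  p = numeric(0), maf = numeric(0), n_markers = integer(0),
                  pct_var = numeric(0))
  class(res) <- c("qtl_record", "data.frame")
  res
}

#' Percentage of variance explained by a top SNP
#'
#' `100 * 2p(1-p) * alpha^2 / var_sire`: the genetic variance contributed
#' by a biallelic locus with minor allele frequency `p` and allele
#' substitution effect `alpha`, relative to the variance of the sire
#' performances.
#'
#' @param p minor allele frequency, in `[0, 0.5]`.
#' @param alpha allele substitution effect (trait units per minor allele).
#' @param var_sire variance of the sire means (must be positive).
#' @return percent of variance explained.
#' @examples
#' variance_explained(0.5, 1, 1) # 50
#' @export
variance_explained <- function(p, alpha, var_sire) {
  if (any(var_sire <= 0)) stop("var_sire must be positive")
  stopifnot(all(p >= 0), all(p <= 0.5))
  100 * 2 * p * (1 - p) * alpha^2 / var_sire
}

#' Merge QTL across traits and conditions into a catalogue
#'
#' QTL whose confidence intervals overlap on the same chromosome are given
#' a single catalogue identity (transitive closure: if A overlaps B and B
#' overlaps C, all three merge even when A and C are disjoint). Catalogue
#' ids are assigned deterministically by chromosome then position.
#'
#' @param qtls data.frame of QTL rows (as [call_qtls()]) with additional
#'   columns `trait` and/or `condition` if available.
#' @return data.frame: `qtl_id`, `chr`, `ci_start`, `ci_end` (union of the
#'   members' intervals), `traits`, `conditions`, `n_members`, plus a
#'   `members` list-column of row indices into `qtls`.
#' @export
merge_across_traits <- function(qtls) {
  if (nrow(qtls) == 0)
    return(data.frame(qtl_id = character(0), chr = character(0),
                      ci_start = numeric(0), ci_end = numeric(0),
                      traits = character(0), conditions = character(0),
                      n_members = integer(0)))
  n <- nrow(qtls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (qtls$chr[i] == qtls$chr[j] &&
        qtls$ci_start[i] <= qtls$ci_end[j] &&
        qtls$ci_start[j] <= qtls$ci_end[i]) union_(i, j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  rows <- lapply(groups, function(jj) {
    data.frame(
      chr = qtls$chr[jj[1]],
      ci_start = min(qtls$ci_start[jj]), ci_end = max(qtls$ci_end[jj]),
      traits = paste(sort(unique(as.character(qtls$trait[jj] %||% "NA"))),
                     collapse = ","),
      conditions = paste(sort(unique(as.character(qtls$condition[jj] %||% "ALL"))),
                         collapse = ","),
      n_members = length(jj))
  })
  cat_tab <- do.call(rbind, rows)
  ord <- order(cat_tab$chr, cat_tab$ci_start)
  cat_tab <- cat_tab[ord, , drop = FALSE]
  cat_tab <- cbind(qtl_id = sprintf("QTL%d", seq_len(nrow(cat_tab))), cat_tab)
  cat_tab$members <- I(unname(groups[ord]))
  rownames(cat_tab) <- NULL
  cat_tab
}
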