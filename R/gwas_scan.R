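#' REML variance components of the null sire-mean model
#'
#' Fits `z = 1*mu + e`, `V(e) = A*sigma2_g + I*sigma2_e`, by restricted
#' maximum likelihood. The likelihood is profiled over the variance ratio
#' `lambda = sigma2_g / sigma2_e` using one eigendecomposition of A, which
#' can be precomputed and shared across traits and conditions.
#'
#' @param z named numeric vector of sire means (names = sire ids), or a
#'   data.frame from [sire_means()] restricted to one condition.
#' @param A additive relationship matrix covering at least the sires in
#'   `z`.
#' @param eig optional `eigen(A[ids, ids], symmetric = TRUE)` result for
#'   exactly the sires of `z` in order, to reuse across traits.
#' @param lambda_bounds search interval for `log10(lambda)`.
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `lambda`, `loglik` (restricted, up to an additive constant),
#'   `n`, `degenerate` (TRUE when the phenotype carries no variance).
#' @export
fit_null_reml <- function(z, A, eig = NULL, lambda_bounds = c(-6, 6)) {
  if (is.data.frame(z)) {
    stopifnot(length(unique(z$condition)) == 1)
    z <- stats::setNames(z$mean, z$sire)
  }
  ids <- names(z)
  stopifnot(!is.null(ids), all(ids %in% rownames(A)) || !is.null(eig))
  n <- length(z)
  if (n < 2) stop("need at least 2 sires")
  if (stats::sd(z) == 0)
    return(structure(list(sigma2_g = 0, sigma2_e = 0, lambda = 0,
                          loglik = NA_real_, n = n, degenerate = TRUE),
                     class = "variance_components"))
  if (is.null(eig)) eig <- eigen(A[ids, ids], symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ystar <- drop(crossprod(U, z))
  xstar <- drop(crossprod(U, rep(1, n)))

  restricted_ll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    w <- lam * d + 1
    xtx <- sum(xstar^2 / w)
    beta <- sum(xstar * ystar / w) / xtx
    r <- ystar - xstar * beta
    rss <- sum(r^2 / w)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(w)) + log(xtx) + (n - 1))
  }
  opt <- stats::optimize(restricted_ll, interval = lambda_bounds, maximum = TRUE)
  # compare against the boundary (no genetic variance)
  ll_0 <- restricted_ll(lambda_bounds[1])
  if (ll_0 >= opt$objective) {
    opt$maximum <- lambda_bounds[1]
    opt$objective <- ll_0
  }
  lam <- 10^opt$maximum
  w <- lam * d + 1
  xtx <- sum(xstar^2 / w)
  beta <- sum(xstar * ystar / w) / xtx
  rss <- sum((ystar - xstar * beta)^2 / w)
  s2e <- rss / (n - 1)
  s2g <- lam * s2e
  if (opt$maximum <= lambda_bounds[1] + 1e-9) s2g <- 0  # boundary: clip
  structure(list(sigma2_g = s2g, sigma2_e = s2e, lambda = lam,
                 loglik = opt$objective, n = n, degenerate = FALSE),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (REML): sigma2_g = %.4g, sigma2_e = %.4g (n = %d)\n",
              x$sigma2_g, x$sigma2_e, x$n))
  invisible(x)
}

#' Single-marker mixed-model scan
#'
#' For each marker, generalized least squares of the sire means on the
#' minor-allele dosage under `V = A*sigma2_g + I*sigma2_e`, with the
#' variance components held fixed across markers (single-decomposition
#' scan). Sires with a missing call are dropped for that marker only. Wald
#' p-values come from the standard normal, the variance being treated as
#' known.
#'
#' @param z named numeric vector of sire means, or a [sire_means()]
#'   data.frame for one condition.
#' @param g a [genotype_matrix()]; rows covering the sires of `z`.
#' @param A additive relationship matrix.
#' @param vc [fit_null_reml()] result for this trait/condition.
#' @return data.frame of class `assoc_result`: `marker`, `chr`, `bp`,
#'   `maf`, `n`, `alpha`, `se`, `wald`, `p`. Markers monomorphic among the
#'   scanned sires get `NA` estimates.
#' @export
scan_snps <- function(z, g, A, vc) {
  if (is.data.frame(z)) {
    stopifnot(length(unique(z$condition)) == 1)
    z <- stats::setNames(z$mean, z$sire)
  }
  ids <- names(z)
  stopifnot(all(ids %in% rownames(g$dosage)))
  X <- g$dosage[ids, , drop = FALSE]
  n <- length(z)
  V <- vc$sigma2_g * A[ids, ids] + diag(vc$sigma2_e, n)
  if (vc$sigma2_g <= 0 && vc$sigma2_e <= 0)
    stop("degenerate variance components: no residual variance")
  C <- chol(V)                    # V = C'C, whitening via forward solve
  wy <- backsolve(C, z, transpose = TRUE)
  w1 <- backsolve(C, rep(1, n), transpose = TRUE)

  m <- ncol(X)
  alpha <- se <- rep(NA_real_, m)
  nn <- integer(m)
  maf <- rep(NA_real_, m)
  complete <- !colSums(is.na(X))
  if (any(complete)) {
    WX <- backsolve(C, X[, complete, drop = FALSE], transpose = TRUE)
    a11 <- sum(w1^2)
    a12 <- drop(crossprod(WX, w1))
    a22 <- colSums(WX^2)
    b1 <- sum(w1 * wy)
    b2 <- drop(crossprod(WX, wy))
    det <- a11 * a22 - a12^2
    ok <- det > 1e-12 * a11 * pmax(a22, 1e-300)
    est <- (a11 * b2 - a12 * b1) / det
    va <- a11 / det
    alpha[complete] <- ifelse(ok, est, NA_real_)
    se[complete] <- ifelse(ok, sqrt(va), NA_real_)
    nn[complete] <- n
    f <- colMeans(X[, complete, drop = FALSE]) / 2
    maf[complete] <- pmin(f, 1 - f)
  }
  for (j in which(!complete)) {
    use <- !is.na(X[, j])
    xs <- X[use, j]
    nn[j] <- sum(use)
    if (nn[j] < 3 || stats::var(xs) == 0) next
    f <- mean(xs) / 2
    maf[j] <- min(f, 1 - f)
    Vs <- V[use, use]
    Cs <- chol(Vs)
    Xs <- cbind(1, xs)
    WXs <- backsolve(Cs, Xs, transpose = TRUE)
    wys <- backsolve(Cs, z[use], transpose = TRUE)
    XtX <- crossprod(WXs)
    est <- solve(XtX, crossprod(WXs, wys))
    alpha[j] <- est[2]
    se[j] <- sqrt(solve(XtX)[2, 2])
  }
  # monomorphic among scanned sires: flag, no test
  mono <- !is.na(maf) & maf == 0
  alpha[mono] <- NA_real_
  se[mono] <- NA_real_
  res <- data.frame(marker = g$map$marker, chr = g$map$chr, bp = g$map$bp,
                    maf = maf, n = nn, alpha = alpha, se = se)
  res$wald <- res$alpha / res$se
  res$p <- 2 * stats::pnorm(-abs(res$wald))
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (chromosomes or markers).
#' @return `alpha / m`, exactly.
#' @examples
#' bonferroni_level(0.05, 32) # 0.0015625
#' @export
bonferroni_level <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Monte-Carlo chromosome-wide p-value threshold
#'
#' Calibrates a per-chromosome significance threshold that accounts for the
#' correlation between marker tests. The vector of per-marker Wald
#' statistics is simulated from its null distribution -- multivariate
#' normal with correlation equal to the correlation of the GLS-whitened,
#' intercept-residualized genotype columns -- and the threshold is the
#' `level`-quantile of the per-draw minimum p-value. With one marker (or
#' perfectly correlated markers) this reduces to `level`; with independent
#' markers it approaches the Sidak bound.
#'
#' @param g_chr [genotype_matrix()] restricted to one chromosome.
#' @param vc variance components ([fit_null_reml()]).
#' @param A relationship matrix over the scan's sires.
#' @param ids sire ids used in the scan (rows of the dosage matrix).
#' @param level chromosome-wide error rate (default 0.01).
#' @param n_draws Monte-Carlo draws; must be at least `1/level`.
#' @param seed RNG seed.
#' @return p-value threshold (scalar).
#' @export
chromosome_threshold <- function(g_chr, vc, A, ids = rownames(g_chr$dosage),
                                 level = 0.01, n_draws = 2000, seed = 1) {
  if (n_draws < 1 / level)
    stop("n_draws too small for the requested level (need >= 1/level)")
  X <- g_chr$dosage[ids, , drop = FALSE]
  X[is.na(X)] <- rep(colMeans(X, na.rm = TRUE), each = nrow(X))[is.na(X)]
  n <- nrow(X)
  V <- vc$sigma2_g * A[ids, ids] + diag(vc$sigma2_e, n)
  C <- chol(V)
  WX <- backsolve(C, X, transpose = TRUE)
  w1 <- backsolve(C, rep(1, n), transpose = TRUE)
  # residualize on the whitened intercept
  WX <- WX - outer(w1, drop(crossprod(WX, w1)) / sum(w1^2))
  sds <- sqrt(colSums(WX^2))
  keep <- sds > 1e-10
  if (!any(keep)) return(level)  # no testable marker: single-test level
  WX <- sweep(WX[, keep, drop = FALSE], 2, sds[keep], "/")
  R <- crossprod(WX)             # correlation of the null Wald statistics
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  m <- ncol(R)
  with_seed(seed, {
    Zs <- matrix(stats::rnorm(n_draws * m), n_draws, m) %*% t(L)
    minp <- 2 * stats::pnorm(-apply(abs(Zs), 1, max))
    unname(stats::quantile(minp, level, type = 1))
  })
}

#' Threshold set for a whole scan
#'
#' Per chromosome: the 1 % chromosome-wide threshold and the genome-wide
#' threshold, defined as the same machinery run at level
#' `genome_alpha / n_chromosomes` (Bonferroni over chromosomes). Chromosome
#' labels listed in `unknown_groups` instead get the plain Bonferroni
#' per-marker level `genome_alpha / m_group` for both.
#'
#' @param g [genotype_matrix()] (all chromosomes of the scan).
#' @param vc,A,ids as in [chromosome_threshold()].
#' @param chrom_level chromosome-wide error rate (default 0.01).
#' @param genome_alpha genome-wide error rate (default 0.05).
#' @param n_chromosomes denominator of the genome-wide Bonferroni; default
#'   the number of chromosomes present.
#' @param method `"montecarlo"` (default) or `"bonferroni"` (per-marker
#'   Bonferroni within chromosome, no correlation adjustment).
#' @param n_draws,seed Monte-Carlo controls.
#' @param unknown_groups chromosome labels treated as unplaced-marker
#'   groups.
#' @return data.frame of class `threshold_set`: `chr`, `n_markers`,
#'   `chrom_threshold`, `genome_threshold`.
#' @export
compute_thresholds <- function(g, vc, A, ids = rownames(g$dosage),
                               chrom_level = 0.01, genome_alpha = 0.05,
                               n_chromosomes = NULL,
                               method = c("montecarlo", "bonferroni"),
                               n_draws = 2000, seed = 1,
                               unknown_groups = character(0)) {
  method <- match.arg(method)
  chrs <- unique(g$map$chr)
  if (is.null(n_chromosomes)) n_chromosomes <- length(setdiff(chrs, unknown_groups))
  gw_level <- bonferroni_level(genome_alpha, n_chromosomes)
  seeds <- split_seed(seed, 2 * length(chrs))
  rows <- lapply(seq_along(chrs), function(k) {
    cc <- chrs[k]
    jj <- which(g$map$chr == cc)
    m <- length(jj)
    if (cc %in% unknown_groups) {
      thr <- bonferroni_level(genome_alpha, m)
      return(data.frame(chr = cc, n_markers = m, chrom_threshold = thr,
                        genome_threshold = thr))
    }
    if (method == "bonferroni") {
      return(data.frame(chr = cc, n_markers = m,
                        chrom_threshold = chrom_level / m,
                        genome_threshold = gw_level / m))
    }
    g_chr <- subset_genotypes(g, markers = jj)
    nd_gw <- max(n_draws, ceiling(2 / gw_level))
    data.frame(
      chr = cc, n_markers = m,
      chrom_threshold = chromosome_threshold(g_chr, vc, A, ids, chrom_level,
                                             max(n_draws, ceiling(2 / chrom_level)),
                                             seeds[2 * k - 1]),
      genome_threshold = chromosome_threshold(g_chr, vc, A, ids, gw_level,
                                              nd_gw, seeds[2 * k]))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("threshold_set", "data.frame")
  res
}
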