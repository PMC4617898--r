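#' Model specification for per-hatch fixed-effect adjustment
#'
#' The production-trait model contains sire, diet, battery, column and
#' floor; the quality-trait model adds age class, operator and the
#' covariates W (waiting time between laying and measurement, days) and R
#' (hen age, days). Sire is always retained; the remaining terms are
#' candidates for the P < 0.2 submodel selection.
#'
#' @param trait trait name.
#' @param type `"production"` or `"quality"`.
#' @return list of class `model_spec` with `factors`, `covariates`.
#' @export
model_spec <- function(trait, type = c("production", "quality")) {
  type <- match.arg(type)
  factors <- if (type == "production")
    c("sire", "diet", "battery", "column", "floor")
  else
    c("sire", "diet", "age", "battery", "column", "floor", "operator")
  covariates <- if (type == "production") character(0) else c("W", "R")
  structure(list(trait = trait, type = type, factors = factors,
                 covariates = covariates), class = "model_spec")
}

#' Fit the fixed-effect adjustment model for one hatch
#'
#' Least-squares fit of the trait on sire plus the candidate environmental
#' terms, with sum-to-zero factor coding and mean-centred covariates so
#' that the fitted environmental part is expressed as deviations around the
#' hatch mean. Each non-sire term gets a Type-II F test (equivalent to
#' `drop1` here since the models contain no interactions).
#'
#' @param records data.frame of phenotype records for one trait and one
#'   hatch (columns per [simulate_dataset()]).
#' @param spec a [model_spec()].
#' @return list with `fit` (the `lm`), `p_values` (named, non-sire terms),
#'   `terms_used`, `coding = "sum-to-zero"` and `covariate_means`.
#' @export
fit_fixed_model <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- records
  dat$value <- as.numeric(dat$value)
  keep_factor <- character(0)
  for (f in spec$factors) {
    if (!f %in% names(dat)) next
    lv <- unique(dat[[f]][!is.na(dat[[f]])])
    if (f == "sire" || length(lv) >= 2) {
      dat[[f]] <- factor(dat[[f]])
      keep_factor <- c(keep_factor, f)
    }
  }
  if (!"sire" %in% keep_factor) stop("records must contain a sire column")
  cov_means <- numeric(0)
  keep_cov <- character(0)
  for (cv in spec$covariates) {
    if (!cv %in% names(dat) || all(is.na(dat[[cv]]))) next
    cov_means[cv] <- mean(dat[[cv]], na.rm = TRUE)
    dat[[cv]] <- dat[[cv]] - cov_means[cv]
    keep_cov <- c(keep_cov, cv)
  }
  rhs <- paste(c(keep_factor, keep_cov), collapse = " + ")
  contr <- stats::setNames(replicate(length(keep_factor), "contr.sum"),
                           keep_factor)
  fit <- stats::lm(stats::as.formula(paste("value ~", rhs)), data = dat,
                   contrasts = as.list(contr))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient adjustment model; aliased: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  nonsire <- setdiff(c(keep_factor, keep_cov), "sire")
  pv <- stats::setNames(numeric(0), character(0))
  if (length(nonsire)) {
    dr <- stats::drop1(fit, scope = stats::as.formula(
      paste("~", paste(nonsire, collapse = " + "))), test = "F")
    pv <- stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])
  }
  list(fit = fit, p_values = pv, terms_used = c(keep_factor, keep_cov),
       coding = "sum-to-zero", covariate_means = cov_means, data = dat)
}

# Environmental (non-sire) fitted part of a model, per record, including
# the intercept: what adjustment subtracts from the raw values.
environmental_fit <- function(fitobj) {
  fit <- fitobj$fit
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  sire_cols <- grepl("^sire", colnames(X))
  drop(X[, !sire_cols, drop = FALSE] %*% beta[!sire_cols])
}

#' Select the P < 0.2 submodel and adjust records
#'
#' For each hatch separately: fits the full candidate model, retains the
#' environmental terms with p below `p_keep` (sire is always retained),
#' refits the submodel, and subtracts every retained non-sire effect --
#' factor effects as sum-to-zero deviations, covariates at their
#' mean-centred values, plus the intercept -- so that an adjusted value is
#' the sire contribution plus residual. Records further than `sd_trim`
#' phenotypic standard deviations from the adjusted mean (per hatch) are
#' then discarded, once, after adjustment.
#'
#' @param records data.frame of records for one trait (all hatches).
#' @param spec a [model_spec()].
#' @param p_keep retain environmental terms with p below this (default 0.2).
#' @param sd_trim outlier cut in standard deviations (default 4).
#' @return list with `records` (input rows plus `adjusted`), `excluded`
#'   (trimmed rows with `reason`), and `models` (per-hatch summaries:
#'   retained terms and p-values).
#' @export
select_and_adjust <- function(records, spec, p_keep = 0.2, sd_trim = 4.0) {
  stopifnot(nrow(records) > 0)
  out <- list(); excl <- list(); models <- list()
  for (h in unique(records$hatch)) {
    rec_h <- records[records$hatch == h, , drop = FALSE]
    full <- fit_fixed_model(rec_h, spec)
    retained <- names(full$p_values)[full$p_values < p_keep]
    sub_spec <- spec
    sub_spec$factors <- intersect(spec$factors, c("sire", retained))
    sub_spec$covariates <- intersect(spec$covariates, retained)
    sub <- fit_fixed_model(rec_h, sub_spec)
    rec_h$adjusted <- rec_h$value - environmental_fit(sub)
    mu <- mean(rec_h$adjusted)
    sdv <- stats::sd(rec_h$adjusted)
    off <- if (is.na(sdv) || sdv == 0) rep(FALSE, nrow(rec_h))
           else abs(rec_h$adjusted - mu) > sd_trim * sdv
    if (any(off)) {
      ex <- rec_h[off, , drop = FALSE]
      ex$reason <- sprintf("beyond %.1f SD of adjusted mean", sd_trim)
      excl[[length(excl) + 1L]] <- ex
    }
    out[[length(out) + 1L]] <- rec_h[!off, , drop = FALSE]
    models[[h]] <- list(hatch = h, p_values = full$p_values,
                        retained = retained, coding = sub$coding)
  }
  adjusted <- do.call(rbind, out)
  sires_lost <- setdiff(unique(records$sire), unique(adjusted$sire))
  if (length(sires_lost))
    warning("all records removed for sire(s): ",
            paste(sires_lost, collapse = ", "))
  list(records = adjusted,
       excluded = if (length(excl)) do.call(rbind, excl) else NULL,
       models = models)
}

#' Per-sire means of adjusted records
#'
#' The daughter-design sire "performance": arithmetic mean of a sire's
#' daughters' adjusted values, either over all records (`ALL`) or within
#' condition (diets `HE`/`LE`, or age classes `AGE50`/`AGE70`).
#'
#' @param adjusted data.frame with columns `sire`, `adjusted` and, as
#'   needed, `diet` / `age`.
#' @param grouping `"ALL"`, `"by-diet"` or `"by-age"`.
#' @return data.frame `sire`, `condition`, `mean`, `n_records`; groups with
#'   zero records are omitted.
#' @export
sire_means <- function(adjusted, grouping = c("ALL", "by-diet", "by-age")) {
  grouping <- match.arg(grouping)
  grp <- switch(grouping,
    "ALL" = rep("ALL", nrow(adjusted)),
    "by-diet" = as.character(adjusted$diet),
    "by-age" = paste0("AGE", adjusted$age))
  ok <- !is.na(grp) & grp != "AGENA"
  agg <- stats::aggregate(adjusted$adjusted[ok],
                          by = list(sire = adjusted$sire[ok], condition = grp[ok]),
                          FUN = mean)
  cnt <- stats::aggregate(adjusted$adjusted[ok],
                          by = list(sire = adjusted$sire[ok], condition = grp[ok]),
                          FUN = length)
  res <- data.frame(sire = agg$sire, condition = agg$condition,
                    mean = agg$x, n_records = cnt$x)
  res[order(res$condition, res$sire), , drop = FALSE]
}
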