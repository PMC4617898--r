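#' Genotype matrix container
#'
#' Bundles a sires-by-markers minor-allele dosage matrix with its marker map.
#' Dosages count copies of the minor allele (0, 1, 2) with `NA` for missing
#' calls. The map gives, for every column of the matrix, the marker id,
#' chromosome label (an opaque string, so linkage groups and "unknown" need
#' no special casing) and 1-based physical position.
#'
#' @param dosage numeric matrix, sires in rows, markers in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `marker`, `chr`, `bp`; one row per
#'   column of `dosage`, positions strictly increasing within chromosome.
#' @param sire_ids character vector of row ids; defaults to
#'   `rownames(dosage)`.
#' @return An object of class `genotype_matrix` with elements `dosage`
#'   (dimnamed matrix) and `map`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(marker = c("m1", "m2"), chr = "1", bp = c(100, 200))
#' )
#' @export
genotype_matrix <- function(dosage, map, sire_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(sire_ids)) stop("sire ids are required (rownames or sire_ids)")
  stopifnot(
    nrow(map) == ncol(dosage),
    all(c("marker", "chr", "bp") %in% names(map)),
    !anyDuplicated(map$marker), !anyDuplicated(sire_ids)
  )
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  map$chr <- as.character(map$chr)
  for (cc in unique(map$chr)) {
    pos <- map$bp[map$chr == cc]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  dimnames(dosage) <- list(sire_ids, map$marker)
  structure(list(dosage = dosage, map = map[, c("marker", "chr", "bp")]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "sires x", ncol(x$dosage),
      "markers on", length(unique(x$map$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset a genotype_matrix by sire and/or marker index, keeping map in step.
subset_genotypes <- function(g, sires = NULL, markers = NULL) {
  d <- g$dosage
  m <- g$map
  if (!is.null(sires)) d <- d[sires, , drop = FALSE]
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
    rownames(m) <- NULL
  }
  structure(list(dosage = d, map = m), class = "genotype_matrix")
}

# Minor allele frequency per marker from non-missing dosages. Dosages are
# stored on a fixed allele orientation, so the raw frequency can exceed 0.5
# after subsetting individuals; `folded = TRUE` returns min(f, 1 - f).
marker_maf <- function(g, folded = TRUE) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  if (folded) pmin(f, 1 - f) else f
}
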