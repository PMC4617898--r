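#' Write genotypes as PLINK PED/MAP
#'
#' Whitespace-delimited PED with family and individual id both set to the
#' sire id, unknown parents, male sex and missing phenotype. Alleles are
#' letters: `A` for the major and `B` for the minor allele, `0 0` for a
#' missing call. The MAP file has chromosome, marker id, a zero genetic
#' distance and the bp position.
#'
#' @param g a [genotype_matrix()].
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly the two file paths.
#' @export
write_ped_map <- function(g, prefix) {
  map <- g$map
  utils::write.table(
    data.frame(chr = map$chr, marker = map$marker, cm = 0, bp = map$bp),
    paste0(prefix, ".map"), sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  d <- g$dosage
  a1 <- matrix("A", nrow(d), ncol(d))
  a2 <- matrix("A", nrow(d), ncol(d))
  a1[d >= 1] <- "B"
  a2[d == 2] <- "B"
  a1[is.na(d)] <- "0"
  a2[is.na(d)] <- "0"
  geno_cols <- matrix("", nrow(d), 2 * ncol(d))
  geno_cols[, seq(1, 2 * ncol(d), by = 2)] <- a1
  geno_cols[, seq(2, 2 * ncol(d), by = 2)] <- a2
  lines <- apply(cbind(rownames(d), rownames(d), "0", "0", "1", "-9",
                       geno_cols), 1, paste, collapse = " ")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read genotypes from PLINK PED/MAP
#'
#' Parses a whitespace-delimited PED/MAP pair into a [genotype_matrix()].
#' For each marker the minor allele is determined from the file's observed
#' allele frequencies (ties broken towards the lexicographically larger
#' allele letter), and dosages count that allele, so orientation is always
#' frequency-consistent regardless of the letters used in the file.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return a [genotype_matrix()].
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "marker", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  lines <- readLines(paste0(prefix, ".ped"))
  m <- nrow(map)
  ids <- character(length(lines))
  dosage <- matrix(NA_real_, length(lines), m)
  allele_store <- matrix(NA_character_, 2 * length(lines), m)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("malformed PED line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(f))
    ids[i] <- f[2]
    al <- f[-(1:6)]
    al[al == "0"] <- NA_character_
    allele_store[2 * i - 1, ] <- al[seq(1, 2 * m, 2)]
    allele_store[2 * i, ] <- al[seq(2, 2 * m, 2)]
  }
  for (j in seq_len(m)) {
    al <- allele_store[, j]
    obs <- sort(unique(stats::na.omit(al)))
    if (length(obs) > 2) stop("more than two alleles for marker ", map$marker[j])
    minor <- if (length(obs) == 0) NA_character_
    else if (length(obs) == 1) obs
    else {
      counts <- table(factor(al, levels = obs))
      if (counts[1] == counts[2]) obs[2]   # tie: larger letter
      else names(counts)[which.min(counts)]
    }
    if (!is.na(minor)) {
      d1 <- allele_store[seq(1, 2 * nrow(dosage), 2), j] == minor
      d2 <- allele_store[seq(2, 2 * nrow(dosage), 2), j] == minor
      dosage[, j] <- as.numeric(d1) + as.numeric(d2)
    }
  }
  rownames(dosage) <- ids
  genotype_matrix(dosage, map[, c("marker", "chr", "bp")])
}

#' Write genotypes as VCF v4.2 (GT only)
#'
#' Minimal VCF: `REF=A` (major), `ALT=B` (minor), one `GT` field per sire.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosage
  gt <- matrix("0/0", nrow(d), ncol(d))
  gt[d == 1] <- "0/1"
  gt[d == 2] <- "1/1"
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(g$map$chr[j], g$map$bp[j], g$map$marker[j], "A", "B", ".", ".",
            ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (GT only)
#'
#' @param path VCF path (uncompressed, v4.x, diploid GT).
#' @return a [genotype_matrix()]; dosages count the minor allele as
#'   determined from the observed genotype frequencies (ties towards ALT).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  m <- length(body)
  map <- data.frame(marker = character(m), chr = character(m), bp = integer(m))
  alt_dos <- matrix(NA_real_, length(ids), m)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t")[[1]]
    if (length(f) != 9 + length(ids))
      stop("malformed VCF record at data line ", j)
    map$chr[j] <- f[1]; map$bp[j] <- as.integer(f[2]); map$marker[j] <- f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    al <- strsplit(gt, "[/|]")
    n_al <- lengths(al)
    if (any(n_al != 2)) stop("non-diploid GT in record ", f[3])
    dd <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
    alt_dos[, j] <- dd
  }
  # orient to the minor allele from observed frequencies (ties: keep ALT)
  f_alt <- colMeans(alt_dos, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5
  alt_dos[, flip] <- 2 - alt_dos[, flip]
  rownames(alt_dos) <- ids
  genotype_matrix(alt_dos, map)
}

#' Write / read a pedigree TSV
#'
#' Tab-separated `id`, `sire`, `dam` with a header; unknown parents as `NA`.
#' @param ped pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = "NA")
}

#' Write / read a phenotype record TSV
#'
#' Long-format records as produced by [simulate_dataset()], tab-separated
#' with a header.
#' @param phen phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", stringsAsFactors = FALSE)
  for (cc in intersect(c("age", "diet", "hatch", "battery", "column",
                         "floor", "operator", "sire", "record_id", "trait"),
                       names(ph)))
    ph[[cc]] <- as.character(ph[[cc]])
  ph
}
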