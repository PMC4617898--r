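#' Pipeline configuration
#'
#' Assembles the options for [run_pipeline()]. Either `sim` (a
#' [sim_config()]) to generate data, or input paths to read genotypes
#' (PED/MAP prefix or VCF), pedigree and phenotypes from disk.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional [sim_config()]; when given, the simulate stage runs.
#' @param genotypes,pedigree,phenotypes input paths (used when `sim` is
#'   `NULL`); `genotypes` is a PED/MAP prefix unless it ends in `.vcf`.
#' @param qc named list of [apply_snp_filters()] thresholds.
#' @param scan named list: `chrom_level`, `genome_alpha`, `n_chromosomes`,
#'   `threshold_method`, `n_draws`.
#' @param qtl named list: `gap_tolerance`.
#' @param gxe named list: `z_method`, `star_level`.
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, genotypes = NULL,
                            pedigree = NULL, phenotypes = NULL,
                            qc = list(), scan = list(), qtl = list(),
                            gxe = list(), seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, genotypes = genotypes,
                 pedigree = pedigree, phenotypes = phenotypes, qc = qc,
                 scan = scan, qtl = qtl, gxe = gxe, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' File keys mirror the arguments of [pipeline_config()]; the `sim` block,
#' when present, is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$qtl)) y$sim$qtl <- as.data.frame(y$sim$qtl)
    if (!is.null(y$sim$traits)) y$sim$traits <- as.data.frame(y$sim$traits)
    if (!is.null(y$sim$n_markers_per_chromosome))
      y$sim$n_markers_per_chromosome <- unlist(y$sim$n_markers_per_chromosome)
    sim <- do.call(sim_config, y$sim)
  }
  pipeline_config(out_dir = y$out_dir %||% ".", sim = sim,
                  genotypes = y$genotypes, pedigree = y$pedigree,
                  phenotypes = y$phenotypes, qc = y$qc %||% list(),
                  scan = y$scan %||% list(), qtl = y$qtl %||% list(),
                  gxe = y$gxe %||% list(), seed = y$seed %||% 1L)
}

#' Run the full daughter-design analysis pipeline
#'
#' Stages, in order: simulate (or load), SNP quality control, per-hatch
#' phenotype adjustment and sire means, pedigree relationship matrix,
#' whole-data and within-condition mixed-model scans with thresholds, QTL
#' calling, interaction testing, and a merged QTL catalogue. All artifacts
#' are written as TSV under `config$out_dir` together with a plain-text log
#' recording record counts, the filter ledger, thresholds and seeds.
#' Re-running with the same configuration reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory artifacts: `qc`
#'   report, `sire_means`, `qtls`, `interactions`, `catalogue`,
#'   `correlations` and the per-stage output paths (`files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
  }
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
    p
  }
  say("pipeline start, seed = ", config$seed)

  ## stage: simulate or load
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    ped <- sim$pedigree; g <- sim$genotypes; phen <- sim$phenotypes
    write_ped_map(g, file.path(config$out_dir, "genotypes"))
    write_pedigree(ped, file.path(config$out_dir, "pedigree.tsv"))
    write_phenotypes(phen, file.path(config$out_dir, "phenotypes.tsv"))
    say("simulated ", nrow(ped), " pedigree rows, ",
        nrow(g$dosage), " sires x ", ncol(g$dosage), " markers, ",
        nrow(phen), " phenotype records")
  } else {
    g <- if (grepl("\\.vcf$", config$genotypes)) read_vcf(config$genotypes)
    else read_ped_map(config$genotypes)
    ped <- read_pedigree(config$pedigree)
    phen <- read_phenotypes(config$phenotypes)
    say("loaded ", nrow(g$dosage), " sires x ", ncol(g$dosage), " markers, ",
        nrow(phen), " phenotype records")
  }

  ## stage: QC
  qc_args <- config$qc
  qc <- do.call(apply_snp_filters, c(list(g = g), qc_args))
  g <- qc$genotypes
  emit(qc$report$steps, "filter_report.tsv")
  say("QC: ", qc$report$n_markers_initial, " -> ", qc$report$n_markers_final,
      " markers; ", qc$report$n_individuals_initial, " -> ",
      qc$report$n_individuals_final, " individuals")

  ## stage: kinship (genotyped sires plus their pedigree ancestors)
  sires <- rownames(g$dosage)
  A <- build_A(ped)
  say("A matrix over ", nrow(A), " individuals")

  ## stage: adjust + scans per trait
  traits <- unique(phen$trait)
  all_qtls <- list(); all_inter <- list(); all_sm <- list(); cors <- list()
  scan_opts <- config$scan
  for (tr in traits) {
    rec <- phen[phen$trait == tr & phen$sire %in% sires, , drop = FALSE]
    type <- if (all(is.na(rec$age))) "production" else "quality"
    adj <- select_and_adjust(rec, model_spec(tr, type))
    sm_all <- sire_means(adj$records, "ALL")
    sm_diet <- sire_means(adj$records, "by-diet")
    sm_cond <- sm_diet
    if (type == "quality") sm_cond <- rbind(sm_cond, sire_means(adj$records, "by-age"))
    sm_all$trait <- tr; sm_cond$trait <- tr
    all_sm[[tr]] <- rbind(sm_all, sm_cond)
    res <- within_condition_scan_and_augment(
      sm_all[, c("sire", "condition", "mean", "n_records")],
      sm_cond[, c("sire", "condition", "mean", "n_records")],
      g, A, trait = tr,
      chrom_level = scan_opts$chrom_level %||% 0.01,
      genome_alpha = scan_opts$genome_alpha %||% 0.05,
      n_chromosomes = scan_opts$n_chromosomes,
      threshold_method = scan_opts$threshold_method %||% "montecarlo",
      n_draws = scan_opts$n_draws %||% 2000,
      gap_tolerance = config$qtl$gap_tolerance %||% 0,
      z_method = config$gxe$z_method %||% "literal",
      star_level = config$gxe$star_level %||% 0.1,
      seed = config$seed + match(tr, traits))
    say("trait ", tr, ": ", nrow(res$qtls), " QTL (",
        sum(res$qtls$additional), " additional)")
    all_qtls[[tr]] <- res$qtls
    if (!is.null(res$interactions)) all_inter[[tr]] <- res$interactions
    eff <- do.call(rbind, lapply(res$scans, function(s)
      s[, c("marker", "trait", "condition", "alpha")]))
    for (pairing in c("diet", "age")) {
      cr <- condition_correlations(eff, pairing = pairing)
      if (!all(is.na(cr$r))) {
        cr$pairing <- pairing
        cors[[paste(tr, pairing)]] <- cr
      }
    }
  }
  qtls <- do.call(rbind, all_qtls)
  rownames(qtls) <- NULL
  inter <- if (length(all_inter)) do.call(rbind, all_inter) else NULL
  sm_tab <- do.call(rbind, all_sm)
  cat_tab <- merge_across_traits(qtls)
  emit(sm_tab, "sire_means.tsv")
  emit(qtls, "qtls.tsv")
  if (!is.null(inter)) emit(inter, "interactions.tsv")
  emit(cat_tab[, setdiff(names(cat_tab), "members")], "qtl_catalogue.tsv")
  cor_tab <- if (length(cors)) do.call(rbind, cors) else NULL
  if (!is.null(cor_tab)) emit(cor_tab, "condition_correlations.tsv")
  say("catalogue: ", nrow(cat_tab), " merged QTL; ",
      if (is.null(inter)) 0L else sum(inter$p < (config$gxe$star_level %||% 0.1)),
      " significant interaction tests")
  writeLines(log_lines, log_path)
  invisible(list(qc = qc$report, A = A, sire_means = sm_tab, qtls = qtls,
                 interactions = inter, catalogue = cat_tab,
                 correlations = cor_tab, files = files, log = log_path))
}
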