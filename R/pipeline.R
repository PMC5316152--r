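#' Assemble a pipeline configuration
#'
#' A pipeline run either simulates its inputs (set `simulate`) or consumes
#' existing files (`bed_sd_mrna`, `bed_metr_mrna`, `bed_sd_footprint`,
#' `bed_metr_footprint`, `models`, optionally `cds_fasta` and `gmt`). Every
#' analysis threshold is a named field with the pipeline default rather than
#' a constant in code. Configurations round-trip losslessly through YAML
#' ([readPipelineConfig()] / [writePipelineConfig()]).
#'
#' @param outdir output directory (created if needed).
#' @param simulate `NULL`, or a list of [effectConfig()] arguments (at least
#'   `nGenes`) describing the synthetic inputs to generate.
#' @param bed_sd_mrna,bed_metr_mrna,bed_sd_footprint,bed_metr_footprint BED6
#'   read files, required unless `simulate` is set.
#' @param models gene-model TSV path (required unless `simulate`).
#' @param cds_fasta CDS FASTA path (optional; enables the codon stage).
#' @param gmt gene-set GMT path (optional; enables the module stage).
#' @param min_total,k,offset,tss_exclusion,te_z_cutoff,module_z_cutoff
#'   analysis thresholds (defaults 128, 100, 15, 50, 2, 2.5).
#' @param min_module_size,delta,min_evidence,pseudocount,sigma_floor further
#'   thresholds (defaults 15, 1, 16, 0.5, 0.05).
#' @param exclude_ids gene ids excluded from the 5'UTR group summaries.
#' @param seed integer seed for simulation.
#' @return a validated config list of class `ribotrans_config`.
#' @export
pipelineConfig <- function(outdir, simulate = NULL,
                           bed_sd_mrna = NULL, bed_metr_mrna = NULL,
                           bed_sd_footprint = NULL,
                           bed_metr_footprint = NULL,
                           models = NULL, cds_fasta = NULL, gmt = NULL,
                           min_total = 128L, k = 100L, offset = 15L,
                           tss_exclusion = 50L, te_z_cutoff = 2,
                           module_z_cutoff = 2.5, min_module_size = 15L,
                           delta = 1, min_evidence = 16L, pseudocount = 0.5,
                           sigma_floor = 0.05, exclude_ids = character(),
                           seed = 1L) {
  cfg <- list(outdir = outdir, simulate = simulate,
              bed_sd_mrna = bed_sd_mrna, bed_metr_mrna = bed_metr_mrna,
              bed_sd_footprint = bed_sd_footprint,
              bed_metr_footprint = bed_metr_footprint,
              models = models, cds_fasta = cds_fasta, gmt = gmt,
              min_total = min_total, k = k, offset = offset,
              tss_exclusion = tss_exclusion, te_z_cutoff = te_z_cutoff,
              module_z_cutoff = module_z_cutoff,
              min_module_size = min_module_size, delta = delta,
              min_evidence = min_evidence, pseudocount = pseudocount,
              sigma_floor = sigma_floor,
              exclude_ids = as.character(exclude_ids),
              seed = as.integer(seed))
  class(cfg) <- "ribotrans_config"
  validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a config list.
#' @export
validatePipelineConfig <- function(cfg) {
  if (is.null(cfg$outdir)) stopf("config field 'outdir' is required")
  num <- c("min_total", "k", "offset", "tss_exclusion", "te_z_cutoff",
           "module_z_cutoff", "min_module_size", "delta", "min_evidence")
  for (f in num)
    if (is.null(cfg[[f]]) || cfg[[f]] <= 0)
      stopf("config field '%s' must be a positive number", f)
  if (is.null(cfg$simulate)) {
    for (f in c("bed_sd_mrna", "bed_metr_mrna", "bed_sd_footprint",
                "bed_metr_footprint", "models"))
      if (is.null(cfg[[f]]))
        stopf("config field '%s' is required when simulation is off", f)
  } else if (is.null(cfg$simulate$nGenes)) {
    stopf("config field 'simulate$nGenes' is required")
  }
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$exclude_ids <- as.character(cfg$exclude_ids)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "ribotrans_config"
  validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("failed at stage '%s': %s", name,
                       conditionMessage(e)),
               file.path(outdir, "PIPELINE_FAILED"))
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages in dependency order: simulate (optional) -> count -> fold changes
#' (both assays) -> translational efficiency -> module scores (optional) ->
#' 5'UTR occupancy -> codon analysis (optional) -> summary. Each stage writes
#' its TSV into `cfg$outdir` before dependents start; any failure aborts with
#' the stage name and leaves a `PIPELINE_FAILED` marker beside the partial
#' outputs. Re-running an unchanged configuration reproduces byte-identical
#' outputs.
#'
#' The summary mirrors the headline tallies of this kind of study: genes
#' passing the read filter per assay, genes with footprint fold change beyond
#' 4-fold either way, genes with 2-fold TE changes and with `|te_z|` beyond
#' the cutoff, modules beyond the module z cutoff, and loading-class counts.
#'
#' @param cfg a config from [pipelineConfig()]/[readPipelineConfig()], or a
#'   YAML path.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `summary` (named numeric vector), `tables`
#'   (the in-memory stage outputs) and `paths` (files written).
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  validatePipelineConfig(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "PIPELINE_FAILED"))
  say <- function(...) if (!quiet) message(...)
  paths <- character()
  put <- function(name) {
    p <- file.path(outdir, name)
    paths[[name]] <<- p
    p
  }

  sequences <- NULL; gmt <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    say("stage simulate")
    sim <- .stage("simulate", outdir, {
      args <- cfg$simulate
      args$seed <- if (is.null(args$seed)) cfg$seed else as.integer(args$seed)
      ecfg <- do.call(effectConfig, args)
      simulateExperiment(ecfg)
    })
    models <- sim$models
    sequences <- sim$sequences
    truth <- sim$truth
    reads <- sim$reads
    writeGeneModels(models, put("models.tsv"))
    Biostrings::writeXStringSet(sequences, put("cds.fasta"))
    writeTsv(truth, put("truth.tsv"))
    for (lib in LIBRARIES)
      writeBed(reads[[lib]], put(sprintf("reads_%s.bed", lib)))
  } else {
    say("stage load")
    models <- .stage("load", outdir, readGeneModels(cfg$models))
    reads <- .stage("load", outdir, c(
      SD.mRNA = cfg$bed_sd_mrna, MetR.mRNA = cfg$bed_metr_mrna,
      SD.footprint = cfg$bed_sd_footprint,
      MetR.footprint = cfg$bed_metr_footprint))
    if (!is.null(cfg$cds_fasta))
      sequences <- .stage("load", outdir,
                          Biostrings::readDNAStringSet(cfg$cds_fasta))
  }
  if (!is.null(cfg$gmt)) gmt <- .stage("load", outdir, readGmt(cfg$gmt))

  say("stage count")
  counts <- .stage("count", outdir,
    buildCountTable(reads, models, offset = cfg$offset,
                    tssExclusion = cfg$tss_exclusion))
  writeCountTable(counts, put("counts.tsv"))

  say("stage diffexp")
  fc <- .stage("diffexp", outdir, {
    lapply(setNames(ASSAYS, ASSAYS), function(a)
      foldChangeTable(counts, a, minTotal = cfg$min_total, k = cfg$k,
                      pseudocount = cfg$pseudocount,
                      sigmaFloor = cfg$sigma_floor))
  })
  writeTsv(fc$mRNA, put("fc_mrna.tsv"))
  writeTsv(fc$footprint, put("fc_footprint.tsv"))

  say("stage te")
  te <- .stage("te", outdir, teTable(fc$mRNA, fc$footprint))
  writeTsv(te, put("te.tsv"))

  modules <- NULL
  if (!is.null(gmt)) {
    say("stage modules")
    modules <- .stage("modules", outdir, {
      do.call(rbind, lapply(ASSAYS, function(a)
        scoreAllModules(setNames(fc[[a]]$F, fc[[a]]$gene_id), gmt,
                        minSize = cfg$min_module_size, assay = a)))
    })
    writeTsv(modules, put("modules.tsv"))
  }

  say("stage utr")
  utr <- .stage("utr", outdir,
    utrTable(counts, te, delta = cfg$delta, teZCutoff = cfg$te_z_cutoff,
             minEvidence = cfg$min_evidence, pseudocount = cfg$pseudocount))
  writeTsv(utr, put("utr.tsv"))
  utrSummary <- .stage("utr", outdir,
    groupRatioSummary(utr, counts, excludeIds = cfg$exclude_ids))
  writeTsv(utrSummary, put("utr_group_summary.tsv"))

  codonStats <- NULL; codonCor <- NULL
  if (!is.null(sequences)) {
    say("stage codons")
    codonStats <- .stage("codons", outdir, codonFrequencies(sequences))
    writeTsv(codonStats, put("codon_stats.tsv"))
    codonCor <- .stage("codons", outdir, {
      do.call(rbind, lapply(c("KQE", "K", "Q", "E", "M"), function(v)
        correlateFrequencyTE(codonStats, te, v)))
    })
    writeTsv(codonCor, put("codon_correlations.tsv"))
  }

  say("stage summary")
  fp <- fc$footprint
  s <- c(
    n_genes = nrow(models),
    n_filtered_mrna = nrow(fc$mRNA),
    n_filtered_footprint = nrow(fp),
    n_fp_fc_gt4 = sum(fp$F > 4),
    n_fp_fc_lt_quarter = sum(fp$F < 0.25),
    n_te_up_2fold = sum(te$te_ratio > 2),
    n_te_down_2fold = sum(te$te_ratio < 0.5),
    n_te_z_up = sum(te$te_z > cfg$te_z_cutoff),
    n_te_z_down = sum(te$te_z < -cfg$te_z_cutoff),
    n_modules_up = if (is.null(modules)) NA_real_
                   else sum(modules$z > cfg$module_z_cutoff),
    n_modules_down = if (is.null(modules)) NA_real_
                     else sum(modules$z < -cfg$module_z_cutoff),
    n_class1 = sum(utr$loading_class == "class1"),
    n_class2 = sum(utr$loading_class == "class2"),
    n_class3 = sum(utr$loading_class == "class3"))
  summaryDf <- data.frame(metric = names(s), value = as.numeric(s),
                          stringsAsFactors = FALSE)
  writeTsv(summaryDf, put("summary.tsv"))

  invisible(list(summary = s,
                 tables = list(counts = counts, fc = fc, te = te,
                               modules = modules, utr = utr,
                               utr_summary = utrSummary,
                               codon_stats = codonStats,
                               codon_correlations = codonCor,
                               truth = truth),
                 paths = paths))
}
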