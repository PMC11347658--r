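## Config-driven end-to-end runs with a reproducibility report.
##
## Stage outputs are plain files under the output directory (no hidden
## state), so any stage can be rerun in isolation; the run report records
## versions, seeds and a content hash for every file written.

.PIPELINE_STAGES <- c("simulate", "qc", "matrices", "enrich", "de",
                      "gsea", "proportions", "predict")

.STAGE_DEPS <- list(
  simulate = character(0),
  qc = "simulate",
  matrices = "qc",
  enrich = "matrices",
  de = "qc",
  gsea = "de",
  proportions = "qc",
  predict = "matrices"
)

#' @noRd
.configDefaults <- function() {
  list(
    seed = 0,
    outdir = NULL,
    fdr = 0.1,
    stages = .PIPELINE_STAGES,
    simulate = list(nDonors = 8, ageRange = c(25, 70),
                    studyLabels = "this_study", sitesPerDonor = 2,
                    cellsPerSample = 300, nChrom = 5, genesPerChrom = 40,
                    peaksPerGene = 5, nMotifs = 50, motifDensity = 0.05,
                    truthArgs = list()),
    qc = list(k = 7),
    enrich = list(cellTypes = NULL, terms = c("age", "sex")),
    de = list(cellTypes = NULL, terms = c("age", "sex"), meta = FALSE),
    gsea = list(gmt = NULL, nPerm = 1000, deTerm = "age", deCellType = NULL),
    proportions = list(meta = FALSE),
    predict = list(hyperparameters = defaultHyperparameters(),
                   cvFolds = 10, fractions = c(0.8, 0.1, 0.1),
                   cellTypes = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a list, checks it against the config schema
#' (unknown keys rejected, types and ranges checked), fills documented
#' defaults, and either returns the resolved config or raises one error
#' listing every violation found.
#'
#' @param config path to a JSON config file, or a list
#' @return the resolved config list (class \code{PipelineConfig})
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or JSON path",
                             call. = FALSE)
  defaults <- .configDefaults()
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  for (blk in c("simulate", "qc", "enrich", "de", "gsea", "proportions",
                "predict")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad) > 0L) {
        problems <- c(problems, paste0("unknown key(s) in '", blk, "': ",
                                       paste(bad, collapse = ", ")))
      }
      defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  for (key in c("seed", "outdir", "fdr", "stages")) {
    if (!is.null(config[[key]])) defaults[[key]] <- config[[key]]
  }
  cfg <- defaults

  if (is.null(cfg$outdir) || !is.character(cfg$outdir)) {
    problems <- c(problems, "outdir is required and must be a path")
  }
  if (!is.numeric(cfg$fdr) || length(cfg$fdr) != 1 || cfg$fdr <= 0 ||
      cfg$fdr > 1) {
    problems <- c(problems, "fdr must be in (0,1]")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    problems <- c(problems, "seed must be a single integer")
  }
  badStage <- setdiff(cfg$stages, .PIPELINE_STAGES)
  if (length(badStage) > 0L) {
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(badStage, collapse = ", ")))
  }
  if (!is.null(cfg$simulate$nDonors) && cfg$simulate$nDonors < 2) {
    problems <- c(problems, "simulate.nDonors must be >= 2")
  }
  if (cfg$qc$k < 1) problems <- c(problems, "qc.k must be >= 1")
  if (cfg$gsea$nPerm < 100) problems <- c(problems, "gsea.nPerm must be >= 100")
  if (length(problems) > 0L) {
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Write a config back to JSON (round-trips through validateConfig)
#'
#' @param config a validated config
#' @param path output JSON path
#' @export
writeConfig <- function(config, path) {
  cfg <- unclass(config)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @noRd
.stageFiles <- function(outdir) {
  list(
    simulate = file.path(outdir, "study", "cells.tsv"),
    qc = file.path(outdir, "qc", "rna_kept.tsv"),
    matrices = file.path(outdir, "matrices", "motif_counts.mtx"),
    de = file.path(outdir, "de", "de_tests.tsv"),
    enrich = file.path(outdir, "enrich", "motif_covariate_tests.tsv"),
    gsea = file.path(outdir, "gsea", "gsea_results.tsv"),
    proportions = file.path(outdir, "proportions", "proportion_tests.tsv"),
    predict = file.path(outdir, "predict", "test_r2.tsv")
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (simulate, qc, matrices, enrich, de, gsea, proportions, predict),
#' reading each stage's inputs from the files earlier stages wrote, and
#' returns a run report listing seeds, per-stage row counts and a content
#' hash for every output file. Re-running with an identical config is
#' byte-identical.
#'
#' @param config validated \code{PipelineConfig} (or something
#'   \code{\link{validateConfig}} accepts)
#' @param stages subset of stages to run (default: config's stages)
#' @return the run report list, invisibly; also written to
#'   \code{outdir/run_report.json}
#' @export
runPipeline <- function(config, stages = NULL) {
  cfg <- validateConfig(config)
  if (is.null(stages)) stages <- cfg$stages
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  marker <- .stageFiles(outdir)
  for (s in stages) {
    for (dep in .STAGE_DEPS[[s]]) {
      if (!dep %in% stages && !file.exists(marker[[dep]])) {
        stop("stage '", s, "' requires outputs of stage '", dep,
             "', which are missing; run it first", call. = FALSE)
      }
    }
  }
  report <- list(
    package = as.character(utils::packageVersion("donorwise")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, fdr = cfg$fdr, stages = stages,
    bh_family = "BH applied within each (cell type x term x analysis) family",
    rows = list()
  )

  for (s in stages) {
    report$rows[[s]] <- switch(s,
      simulate = .stageSimulate(cfg, outdir),
      qc = .stageQc(cfg, outdir),
      matrices = .stageMatrices(cfg, outdir),
      enrich = .stageEnrich(cfg, outdir),
      de = .stageDe(cfg, outdir),
      gsea = .stageGsea(cfg, outdir),
      proportions = .stageProportions(cfg, outdir),
      predict = .stagePredict(cfg, outdir)
    )
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "run_report.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", outdir, "/?"), "", names(hashes))
  report$files <- as.list(hashes)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @noRd
.stageSimulate <- function(cfg, outdir) {
  p <- cfg$simulate
  study <- simulateStudy(
    nDonors = p$nDonors, ageRange = p$ageRange,
    studyLabels = p$studyLabels, sitesPerDonor = p$sitesPerDonor,
    cellsPerSample = p$cellsPerSample, nChrom = p$nChrom,
    genesPerChrom = p$genesPerChrom, peaksPerGene = p$peaksPerGene,
    nMotifs = p$nMotifs, motifDensity = p$motifDensity,
    truthArgs = p$truthArgs, seed = childSeed(cfg$seed, "simulate"))
  writeStudy(study, file.path(outdir, "study"))
  list(cells = nrow(studyCells(study)), genes = nrow(studyGenes(study)),
       peaks = length(studyPeaks(study)))
}

#' @noRd
.loadStudy <- function(outdir, scanPCutoff = 1e-7) {
  readStudy(file.path(outdir, "study"), scanPCutoff = scanPCutoff)
}

#' @noRd
.stageQc <- function(cfg, outdir) {
  study <- .loadStudy(outdir)
  cells <- studyCells(study)
  rna <- filterRnaCells(cells[cells$modality == "RNA", , drop = FALSE])
  atac <- filterAtacCells(cells[cells$modality == "ATAC", , drop = FALSE])
  labeled <- knnLabelTransfer(rna$kept, atac$kept, k = cfg$qc$k)
  qcdir <- file.path(outdir, "qc")
  writeTsv(rna$kept, file.path(qcdir, "rna_kept.tsv"))
  writeTsv(rna$dropped, file.path(qcdir, "rna_dropped.tsv"))
  writeTsv(labeled, file.path(qcdir, "atac_kept.tsv"))
  writeTsv(atac$dropped, file.path(qcdir, "atac_dropped.tsv"))
  list(rna_kept = nrow(rna$kept), rna_dropped = nrow(rna$dropped),
       atac_kept = nrow(labeled), atac_dropped = nrow(atac$dropped))
}

#' @noRd
.stageMatrices <- function(cfg, outdir) {
  study <- .loadStudy(outdir)
  qcdir <- file.path(outdir, "qc")
  rnaKept <- readTsv(file.path(qcdir, "rna_kept.tsv"))
  atacKept <- readTsv(file.path(qcdir, "atac_kept.tsv"))
  mdir <- file.path(outdir, "matrices")
  mcc <- motifCellCounts(motifMatrix(study),
                         atacCounts(study)[, atacKept$cell_id, drop = FALSE])
  writeMtx(mcc, file.path(mdir, "motif_counts.mtx"),
           file.path(mdir, "motif_counts_rows.tsv"),
           file.path(mdir, "motif_counts_cols.tsv"))
  pb <- pseudobulkLog2Tpm(rnaCounts(study)[, rnaKept$cell_id, drop = FALSE],
                          rnaKept$cell_type)
  out <- data.frame(gene_id = rownames(pb$log2tpm), pb$log2tpm,
                    check.names = FALSE)
  writeTsv(out, file.path(mdir, "pseudobulk_log2tpm.tsv"))
  list(motifs = nrow(mcc), atac_cells = ncol(mcc),
       pseudobulk_types = ncol(pb$log2tpm))
}

#' @noRd
.enrichTypes <- function(cfgTypes, cells, minDonors = 2, minCells = 50) {
  types <- sort(unique(cells$cell_type))
  if (!is.null(cfgTypes)) types <- intersect(types, cfgTypes)
  keep <- vapply(types, function(t) {
    sel <- cells$cell_type == t
    sum(sel) >= minCells && length(unique(cells$donor_id[sel])) >= minDonors
  }, logical(1))
  types[keep]
}

#' @noRd
.stageEnrich <- function(cfg, outdir) {
  mdir <- file.path(outdir, "matrices")
  mcc <- readMtx(file.path(mdir, "motif_counts.mtx"),
                 file.path(mdir, "motif_counts_rows.tsv"),
                 file.path(mdir, "motif_counts_cols.tsv"))
  atacKept <- readTsv(file.path(outdir, "qc", "atac_kept.tsv"))
  atacKept$cell_type <- atacKept$transferred_label
  types <- .enrichTypes(cfg$enrich$cellTypes, atacKept)
  cov <- do.call(rbind, lapply(types, function(ct) {
    do.call(rbind, lapply(cfg$enrich$terms, function(term) {
      tab <- testMotifCovariate(mcc, atacKept, ct, term = term,
                                fdr = cfg$fdr)
      if (nrow(tab) > 0) cbind(cell_type = ct, tab) else NULL
    }))
  }))
  dummy <- do.call(rbind, lapply(types, function(ct) {
    tab <- testMotifCelltype(mcc, atacKept, ct, fdr = cfg$fdr)
    if (nrow(tab) > 0) cbind(cell_type = ct, tab) else NULL
  }))
  edir <- file.path(outdir, "enrich")
  writeTestTable(cov, file.path(edir, "motif_covariate_tests.tsv"))
  writeTestTable(dummy, file.path(edir, "motif_celltype_tests.tsv"))
  list(covariate_rows = if (is.null(cov)) 0L else nrow(cov),
       celltype_rows = if (is.null(dummy)) 0L else nrow(dummy))
}

#' @noRd
.stageDe <- function(cfg, outdir) {
  study <- .loadStudy(outdir)
  rnaKept <- readTsv(file.path(outdir, "qc", "rna_kept.tsv"))
  types <- .enrichTypes(cfg$de$cellTypes, rnaKept)
  de <- do.call(rbind, lapply(types, function(ct) {
    do.call(rbind, lapply(cfg$de$terms, function(term) {
      tab <- deTestGenes(rnaCounts(study), rnaKept, ct, term = term,
                         meta = isTRUE(cfg$de$meta), fdr = cfg$fdr)
      if (nrow(tab) > 0) cbind(cell_type = ct, tab) else NULL
    }))
  }))
  writeTestTable(de, file.path(outdir, "de", "de_tests.tsv"))
  list(de_rows = if (is.null(de)) 0L else nrow(de))
}

#' @noRd
.stageGsea <- function(cfg, outdir) {
  de <- readTestTable(file.path(outdir, "de", "de_tests.tsv"))
  term <- cfg$gsea$deTerm
  if (!any(startsWith(de$term, term))) term <- de$term[1]
  de <- de[startsWith(de$term, term), , drop = FALSE]
  ct <- cfg$gsea$deCellType %||% de$cell_type[1]
  de <- de[de$cell_type == ct, , drop = FALSE]
  stats <- setNames(de$z, de$feature)
  if (!is.null(cfg$gsea$gmt)) {
    sets <- readGmt(cfg$gsea$gmt)
  } else {
    ## demo gene sets drawn from the tested universe (seeded, documented)
    withr::local_seed(childSeed(cfg$seed, "gsea-demo-sets"))
    sets <- lapply(seq_len(10), function(i) {
      sample(names(stats), min(15, max(3, length(stats) %/% 10)))
    })
    names(sets) <- sprintf("demo_set_%02d", seq_along(sets))
  }
  res <- prerankedGsea(stats, sets, nPerm = cfg$gsea$nPerm,
                       seed = childSeed(cfg$seed, "gsea"))
  writeTestTable(res, file.path(outdir, "gsea", "gsea_results.tsv"))
  list(sets = nrow(res), universe = length(stats), cell_type = ct)
}

#' @noRd
.stageProportions <- function(cfg, outdir) {
  rnaKept <- readTsv(file.path(outdir, "qc", "rna_kept.tsv"))
  data <- cellTypeCounts(rnaKept)
  pdir <- file.path(outdir, "proportions")
  writeTsv(data, file.path(pdir, "proportion_counts.tsv"))
  rows <- list()
  for (term in c("age", "sex")) {
    res <- testProportions(data, term = term,
                           meta = isTRUE(cfg$proportions$meta),
                           fdr = cfg$fdr)
    if (nrow(res$table) > 0) {
      rows[[term]] <- cbind(tested_term = term, res$table)
    }
  }
  tab <- do.call(rbind, rows)
  writeTestTable(tab, file.path(pdir, "proportion_tests.tsv"))
  list(samples = length(unique(data$sample_id)),
       types = length(unique(data$cell_type)), test_rows = nrow(tab))
}

#' @noRd
.stagePredict <- function(cfg, outdir) {
  study <- .loadStudy(outdir,
                      scanPCutoff = cfg$predict$hyperparameters$motifPCutoff)
  pb <- readTsv(file.path(outdir, "matrices", "pseudobulk_log2tpm.tsv"))
  expr <- as.matrix(pb[, -1, drop = FALSE])
  rownames(expr) <- pb$gene_id
  genes <- studyGenes(study)
  types <- cfg$predict$cellTypes %||% colnames(expr)
  split <- splitByChromosome(genes, fractions = cfg$predict$fractions,
                             seed = childSeed(cfg$seed, "split"))
  buildFn <- featureBuilder(genes, studyPeaks(study), motifMatrix(study),
                            coaccessLinks(study))
  rnaKept <- readTsv(file.path(outdir, "qc", "rna_kept.tsv"))
  abundance <- table(rnaKept$cell_type)[types]
  rep <- finalFitAndReport(cfg$predict$hyperparameters, buildFn, expr,
                           genes, split, cellTypes = types,
                           abundance = abundance,
                           cvFolds = cfg$predict$cvFolds,
                           seed = childSeed(cfg$seed, "elasticnet"))
  pdir <- file.path(outdir, "predict")
  writeTestTable(rep$testR2, file.path(pdir, "test_r2.tsv"))
  writeTestTable(rep$coefficients, file.path(pdir, "final_coefficients.tsv"))
  writeTsv(split$assignment, file.path(pdir, "chromosome_split.tsv"))
  if (!is.null(rep$abundanceR2)) {
    writeTestTable(rep$abundanceR2, file.path(pdir, "abundance_r2.tsv"))
  }
  list(cell_types = length(types),
       abundance_cor = rep$abundanceCor %||% NA_real_)
}
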