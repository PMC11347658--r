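## Headline evaluation experiments, shared by the acceptance script and the
## acceptance test suite. Each function regenerates its inputs from scratch
## under the supplied seed and returns plain numbers.

#' Type-I error calibration of the mixed vs fixed-effects NB models
#'
#' Simulates an all-null study (donor random-intercept sd 0.5), fits every
#' gene with the donor-aware NB mixed model and with the fixed-effects-only
#' NB GLM, and reports the empirical fraction of Wald p-values below
#' \code{alpha} for the donor-level sex and age terms.
#'
#' Tests run within one cell type (the most abundant), as the battery does.
#'
#' @param nFeatures number of null genes tested
#' @param nDonors donors in the null cohort
#' @param cellsPerSample cells per (donor, site) sample
#' @param alpha nominal test level
#' @param seed integer seed
#' @return list with \code{mixed} and \code{fixed} empirical type-I error
#'   (pooled over the sex and age terms) and the per-term breakdown
#' @export
calibrationExperiment <- function(nFeatures = 200, nDonors = 8,
                                  cellsPerSample = 150, alpha = 0.05,
                                  seed = 1) {
  st <- simulateStudy(
    nDonors = nDonors, cellsPerSample = cellsPerSample,
    nChrom = 5, genesPerChrom = ceiling(nFeatures / 5), nMotifs = 10,
    truthArgs = list(geneBaselineSd = 0.5),
    seed = childSeed(seed, "calibration"))
  cells <- studyCells(st)
  ## the battery under test runs within one cell type; use the most
  ## abundant one so the NB model is not a cross-type mixture
  rc <- cells[cells$modality == "RNA" &
                cells$cell_type == "cardiomyocyte", ]
  rc$log_depth <- log10(rc$total_umi)
  rna <- rnaCounts(st)
  genes <- rownames(rna)[seq_len(nFeatures)]
  p <- vapply(genes, function(g) {
    y <- as.numeric(rna[g, rc$cell_id])
    fm <- fitNbGlmm(y, rc)
    ff <- fitNbGlm(y, rc)
    pv <- function(fit, term) {
      if (!isTRUE(fit$converged)) return(NA_real_)
      r <- coefRow(fit, term)
      2 * pnorm(-abs(r$estimate / r$se))
    }
    c(pv(fm, "sex"), pv(fm, "age"), pv(ff, "sex"), pv(ff, "age"))
  }, numeric(4))
  rate <- function(i) mean(p[i, ] < alpha, na.rm = TRUE)
  list(
    mixed = mean(p[1:2, ] < alpha, na.rm = TRUE),
    fixed = mean(p[3:4, ] < alpha, na.rm = TRUE),
    mixedSex = rate(1), mixedAge = rate(2),
    fixedSex = rate(3), fixedAge = rate(4),
    nFeatures = nFeatures
  )
}

#' Planted-effect recovery across replicate studies
#'
#' Replicates small studies with planted gene and motif sex effects (log
#' fold 0.5) and measures how often the mixed-model estimate falls within
#' +/- 2 SE of the planted value.
#'
#' @param nReplicates replicate studies; each contributes one gene and one
#'   motif recovery event per planted feature checked
#' @param perStudy planted features examined per study and feature class
#' @param nDonors,cellsPerSample study scale
#' @param seed integer seed
#' @return list with the overall \code{within2se} fraction, per-class
#'   fractions and the number of recovery events
#' @export
recoveryExperiment <- function(nReplicates = 25, perStudy = 2, nDonors = 8,
                               cellsPerSample = 120, seed = 1) {
  events <- list(gene = logical(0), motif = logical(0))
  for (r in seq_len(nReplicates)) {
    st <- simulateStudy(
      nDonors = nDonors, cellsPerSample = cellsPerSample,
      nChrom = 3, genesPerChrom = 5, nMotifs = 10,
      truthArgs = list(nGeneSex = perStudy, geneSexEffect = 0.5,
                       nMotifSex = perStudy, motifSexEffect = 0.5),
      seed = childSeed(seed, paste0("recovery", r)))
    cells <- studyCells(st)
    ## fit within the most abundant cell type, as the battery does
    rc <- cells[cells$modality == "RNA" &
                  cells$cell_type == "cardiomyocyte", ]
    rc$log_depth <- log10(rc$total_umi)
    ac <- cells[cells$modality == "ATAC" &
                  cells$cell_type == "cardiomyocyte", ]
    ac$log_depth <- log10(ac$total_umi)
    truth <- plantedTruth(st)
    mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))

    geneBeta <- truth$geneSexBeta[, 1]
    for (g in names(geneBeta)[geneBeta != 0]) {
      fit <- fitNbGlmm(as.numeric(rnaCounts(st)[g, rc$cell_id]), rc)
      if (!fit$converged) next
      row <- coefRow(fit, "sex")
      events$gene <- c(events$gene,
                       abs(row$estimate - geneBeta[g]) <= 2 * row$se)
    }
    motifBeta <- truth$motifSexBeta
    for (m in names(motifBeta)[motifBeta != 0]) {
      fit <- fitNbGlmm(as.numeric(mcc[m, ac$cell_id]), ac)
      if (!fit$converged) next
      row <- coefRow(fit, "sex")
      events$motif <- c(events$motif,
                        abs(row$estimate - motifBeta[m]) <= 2 * row$se)
    }
  }
  all <- c(events$gene, events$motif)
  list(within2se = mean(all), gene = mean(events$gene),
       motif = mean(events$motif), nEvents = length(all))
}

#' Planted cell-type proportion effect detection
#'
#' A 30-donor cohort with a planted logit-scale sex effect on the
#' cardiomyocyte proportion, tested with the beta-binomial mixed model.
#'
#' @param nDonors donors
#' @param beta planted logit effect
#' @param seed integer seed
#' @return list with the planted type's estimate, q-value and sign check
#' @export
proportionExperiment <- function(nDonors = 30, beta = 1.0, seed = 1) {
  st <- simulateStudy(
    nDonors = nDonors, cellsPerSample = 150,
    nChrom = 3, genesPerChrom = 5, nMotifs = 8,
    truthArgs = list(propSexBeta = c(cardiomyocyte = beta)),
    seed = childSeed(seed, "proportions"))
  cells <- studyCells(st)
  rc <- cells[cells$modality == "RNA", ]
  res <- testProportions(cellTypeCounts(rc), term = "sex")
  row <- res$table[res$table$feature == "cardiomyocyte", ]
  list(estimate = row$estimate, se = row$se, q = row$q,
       signCorrect = sign(row$estimate) == sign(beta),
       detected = row$q < 0.1 && sign(row$estimate) == sign(beta))
}

#' Expression-model recovery, leakage control and the distal advantage
#'
#' Uses a noiseless grammar study (expected log2 TPM exactly linear in
#' motif features) to measure held-out accuracy, the promoter-plus-distal
#' vs promoter-only test R-squared gap, and the pure-noise leakage control.
#'
#' @param seed integer seed
#' @param nNoise pure-noise refits for the leakage control
#' @return list with held-out R2, per-type R2 for both modes, and the
#'   maximum mean held-out R2 across noise replicates
#' @export
expressionModelExperiment <- function(seed = 1, nNoise = 10) {
  st <- simulateStudy(
    nDonors = 4, cellsPerSample = 20, nChrom = 5, genesPerChrom = 24,
    nMotifs = 30, motifDensity = 0.05,
    truthArgs = list(geneBaselineSd = 0, typeNoiseSd = 0),
    seed = childSeed(seed, "grammar"))
  genes <- studyGenes(st)
  expr <- plantedTruth(st)$expectedLog2Tpm
  split <- splitByChromosome(genes, seed = childSeed(seed, "grammar-split"))
  buildFn <- featureBuilder(genes, studyPeaks(st), motifMatrix(st),
                            coaccessLinks(st))
  types <- c("cardiomyocyte", "fibroblast", "neuron")
  rep <- finalFitAndReport(defaultHyperparameters(), buildFn, expr, genes,
                           split, cellTypes = types, cvFolds = 5,
                           seed = childSeed(seed, "grammar-fit"))
  feats <- buildFn(defaultHyperparameters(), "promoter_plus_distal")
  heldout <- fitElasticNet(feats, expr, genes, split,
                           cellType = "cardiomyocyte", cvFolds = 5,
                           seed = childSeed(seed, "grammar-heldout"))
  withr::local_seed(childSeed(seed, "grammar-noise"))
  noiseR2 <- replicate(nNoise, {
    y <- setNames(rnorm(nrow(featureMatrix(feats))),
                  rownames(featureMatrix(feats)))
    fit <- fitElasticNet(feats, y, genes, split, cvFolds = 5,
                         seed = childSeed(seed, "grammar-noise-fit"))
    mean(c(modelR2(fit)[["validation"]], modelR2(fit)[["test"]]))
  })
  list(heldoutR2 = min(modelR2(heldout)[["validation"]],
                       modelR2(heldout)[["test"]]),
       testR2 = rep$testR2,
       distalAlwaysWins = all(rep$testR2$promoter_plus_distal >
                                rep$testR2$promoter_only),
       minDistalGap = min(rep$testR2$promoter_plus_distal -
                            rep$testR2$promoter_only),
       noiseR2 = mean(noiseR2), maxNoiseR2 = max(noiseR2))
}

#' Abundance vs accuracy: downsampling cells per type degrades the model
#'
#' Builds pseudo-bulk profiles from deliberately downsampled cell numbers
#' per type (spanning two orders of magnitude) and correlates test
#' R-squared with abundance.
#'
#' @param seed integer seed
#' @return list with the per-type table and its Spearman correlation
#' @export
abundanceExperiment <- function(seed = 1) {
  st <- simulateStudy(
    nDonors = 8, cellsPerSample = 150, nChrom = 5, genesPerChrom = 24,
    nMotifs = 30,
    truthArgs = list(geneBaselineSd = 0.3, typeNoiseSd = 0.1),
    seed = childSeed(seed, "abundance"))
  cells <- studyCells(st)
  rc <- cells[cells$modality == "RNA", ]
  genes <- studyGenes(st)
  types <- sort(unique(rc$cell_type))
  sizes <- setNames(round(1200 * 0.45^(seq_along(types) - 1)) + 2, types)
  withr::local_seed(childSeed(seed, "abundance-sample"))
  picked <- unlist(lapply(types, function(t) {
    ids <- rc$cell_id[rc$cell_type == t]
    sample(ids, min(sizes[[t]], length(ids)))
  }))
  sub <- rc[rc$cell_id %in% picked, ]
  pb <- pseudobulkLog2Tpm(rnaCounts(st)[, sub$cell_id], sub$cell_type)
  split <- splitByChromosome(genes, seed = childSeed(seed, "abundance-split"))
  buildFn <- featureBuilder(genes, studyPeaks(st), motifMatrix(st),
                            coaccessLinks(st))
  abundance <- table(sub$cell_type)[colnames(pb$log2tpm)]
  rep <- finalFitAndReport(defaultHyperparameters(), buildFn, pb$log2tpm,
                           genes, split,
                           cellTypes = colnames(pb$log2tpm),
                           abundance = abundance, cvFolds = 5,
                           seed = childSeed(seed, "abundance-fit"))
  list(table = rep$abundanceR2, spearman = rep$abundanceCor)
}

#' Byte-level determinism of two identical pipeline runs
#'
#' @param seed integer seed
#' @param baseDir scratch directory for the two runs
#' @return list with \code{identical} flag and the number of files compared
#' @export
determinismExperiment <- function(seed = 1, baseDir = tempfile("determinism")) {
  mkConfig <- function(outdir) list(
    outdir = outdir, seed = seed,
    simulate = list(nDonors = 4, cellsPerSample = 40, nChrom = 5,
                    genesPerChrom = 10, nMotifs = 12,
                    truthArgs = list(nGeneSex = 3, nMotifSex = 2)),
    enrich = list(cellTypes = "cardiomyocyte", terms = "sex"),
    de = list(cellTypes = "cardiomyocyte", terms = "sex"),
    gsea = list(nPerm = 200),
    predict = list(cvFolds = 3))
  d1 <- file.path(baseDir, "run1")
  d2 <- file.path(baseDir, "run2")
  runPipeline(mkConfig(d1))
  runPipeline(mkConfig(d2))
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  same <- identical(sort(f1), sort(f2)) &&
    all(vapply(sort(f1), function(f) {
      identical(unname(tools::md5sum(file.path(d1, f))),
                unname(tools::md5sum(file.path(d2, f))))
    }, logical(1)))
  unlink(baseDir, recursive = TRUE)
  list(identical = same, nFiles = length(f1))
}
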