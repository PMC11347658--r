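## A noiseless grammar study: expected log2 TPM is exactly linear in the
## generator's motif features.
noiselessStudy <- function() {
  if (is.null(.fixtureCache$noiseless)) {
    .fixtureCache$noiseless <- simulateStudy(
      nDonors = 4, cellsPerSample = 20, nChrom = 5, genesPerChrom = 24,
      nMotifs = 30, motifDensity = 0.05,
      truthArgs = list(geneBaselineSd = 0, typeNoiseSd = 0),
      seed = 404)
  }
  .fixtureCache$noiseless
}

test_that("the planted grammar is recovered almost perfectly without noise", {
  st <- noiselessStudy()
  genes <- studyGenes(st)
  expr <- plantedTruth(st)$expectedLog2Tpm
  split <- splitByChromosome(genes, seed = 2)
  feats <- buildFeatures(genes, studyPeaks(st), motifMatrix(st),
                         coaccessLinks(st), mode = "promoter_plus_distal")
  fit <- fitElasticNet(feats, expr, genes, split,
                       cellType = "cardiomyocyte", cvFolds = 5, seed = 1)
  expect_gte(modelR2(fit)[["validation"]], 0.95)
  expect_gte(modelR2(fit)[["test"]], 0.95)
})

test_that("pure-noise responses never look predictable (no split leakage)", {
  st <- noiselessStudy()
  genes <- studyGenes(st)
  split <- splitByChromosome(genes, seed = 2)
  feats <- buildFeatures(genes, studyPeaks(st), motifMatrix(st),
                         coaccessLinks(st), mode = "promoter_plus_distal")
  set.seed(5)
  r2s <- replicate(10, {
    y <- setNames(rnorm(nrow(featureMatrix(feats))),
                  rownames(featureMatrix(feats)))
    fit <- fitElasticNet(feats, y, genes, split, cvFolds = 5, seed = 1)
    c(modelR2(fit)[["validation"]], modelR2(fit)[["test"]])
  })
  expect_lte(max(rowMeans(r2s)), 0.05)
})

test_that("a dominant single motif earns the largest positive coefficient", {
  set.seed(8)
  n <- 80
  x <- Matrix::Matrix(matrix(runif(n * 10) < 0.4, n, 10,
                             dimnames = list(sprintf("g%02d", 1:n),
                                             sprintf("m%02d", 1:10))) * 1,
                      sparse = TRUE)
  y <- setNames(as.numeric(x[, 3]) * 1 + rnorm(n, 0, 0.05), rownames(x))
  feats <- new("MotifFeatures", matrix = x, mode = "promoter_only",
               hyperparameters = defaultHyperparameters(),
               provenance = setNames(vector("list", n), rownames(x)))
  genes <- data.frame(gene_id = rownames(x),
                      chrom = rep(sprintf("c%d", 1:8), each = 10),
                      stringsAsFactors = FALSE)
  split <- splitByChromosome(genes, seed = 3)
  fit <- fitElasticNet(feats, y, genes, split, cvFolds = 5, seed = 2)
  b <- modelCoefficients(fit)
  expect_equal(names(which.max(b)), "m03")
  expect_gt(b[["m03"]], 0)
  expect_gt(b[["m03"]], max(abs(b[setdiff(names(b), "m03")])))
})

test_that("degenerate inputs are rejected", {
  st <- noiselessStudy()
  genes <- studyGenes(st)
  split <- splitByChromosome(genes, seed = 2)
  feats <- buildFeatures(genes, studyPeaks(st), motifMatrix(st),
                         coaccessLinks(st))
  y <- setNames(rep(1, nrow(featureMatrix(feats))),
                rownames(featureMatrix(feats)))
  expect_error(fitElasticNet(feats, y, genes, split, cvFolds = 5),
               "zero-variance")
  few <- genes[1:10, ]
  expect_error(
    fitElasticNet(feats, setNames(rnorm(10), few$gene_id), few, split),
    "fewer than 20")
})

test_that("the hyperparameter grids enumerate the full search space", {
  pg <- promoterGrid()
  expect_equal(nrow(pg), 9)
  expect_setequal(unique(pg$promoterUpstream), c(1000, 1500, 5000))
  expect_setequal(unique(pg$motifPCutoff), c(1e-4, 1e-5, 1e-6))
  dg <- distalGrid()
  expect_equal(nrow(dg), 54)
  expect_setequal(unique(dg$coaccCutoff), c(0.015, 0.035, 0.05))
  expect_setequal(unique(dg$maxDistal), c(5, 10, 20))
  expect_setequal(unique(dg$distalWindow), c(600, 1000))
  expect_true(all(dg$promoterUpstream == 1500 & dg$promoterDownstream == 500))
  hp <- defaultHyperparameters()
  expect_equal(hp$promoterUpstream, 1500)
  expect_equal(hp$motifPCutoff, 1e-4)
  expect_equal(hp$coaccCutoff, 0.015)
  expect_equal(hp$maxDistal, 20)
  expect_equal(hp$distalWindow, 1000)
})

test_that("the search prefers configurations that include distal sites", {
  st <- noiselessStudy()
  genes <- studyGenes(st)
  expr <- plantedTruth(st)$expectedLog2Tpm[, c("cardiomyocyte",
                                               "fibroblast")]
  split <- splitByChromosome(genes, seed = 2)
  buildFn <- featureBuilder(genes, studyPeaks(st), motifMatrix(st),
                            coaccessLinks(st))
  grid <- rbind(promoterGrid()[c(1, 5), ], distalGrid()[c(9, 27), ])
  res <- hyperparameterSearch(grid, buildFn, expr, genes, split,
                              cvFolds = 5, seed = 3)
  expect_equal(nrow(res$table), 4)
  expect_equal(res$bestMode, "promoter_plus_distal")
  bestProm <- max(res$table$mean_validation_r2[
    res$table$mode == "promoter_only"], na.rm = TRUE)
  expect_gt(res$table$mean_validation_r2[res$bestIdx], bestProm)
})

test_that("final report shows the distal advantage and recovers signs", {
  st <- noiselessStudy()
  genes <- studyGenes(st)
  truth <- plantedTruth(st)
  expr <- truth$expectedLog2Tpm
  split <- splitByChromosome(genes, seed = 2)
  buildFn <- featureBuilder(genes, studyPeaks(st), motifMatrix(st),
                            coaccessLinks(st))
  types <- c("cardiomyocyte", "fibroblast", "neuron")
  rep <- finalFitAndReport(defaultHyperparameters(), buildFn, expr, genes,
                           split, cellTypes = types, cvFolds = 5, seed = 4)
  ## distal-acting planted signal: promoter-plus-distal wins in every type
  expect_true(all(rep$testR2$promoter_plus_distal >
                    rep$testR2$promoter_only))
  ## planted repressor motifs come back with negative final coefficients
  gm <- studyMetadata(st)$grammar
  for (ct in types) {
    beta <- truth$grammarPromoterBeta[ct, gm$promoter] +
      truth$grammarDistalBeta[ct, gm$promoter]
    est <- rep$coefficients$coefficient[
      rep$coefficients$cell_type == ct][
        match(gm$promoter, rep$coefficients$motif[
          rep$coefficients$cell_type == ct])]
    keep <- abs(beta) > 0.8 & abs(est) > 0.05
    expect_gt(sum(keep), 0)
    expect_true(all(sign(est[keep]) == sign(beta[keep])))
  }
})
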