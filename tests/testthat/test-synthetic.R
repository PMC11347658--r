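test_that("cohort generation respects size, balance and determinism", {
  expect_error(generateCohort(nDonors = 1), "too small")
  expect_error(generateCohort(ageRange = c(70, 25)), "ageRange")

  co <- generateCohort(nDonors = 8, ageRange = c(25, 70),
                       studyLabels = "this_study", seed = 1)
  expect_equal(nrow(co), 8)
  expect_setequal(unique(co$sex), c("F", "M"))
  expect_true(all(co$age >= 25 & co$age <= 70))
  expect_false(anyDuplicated(co$donor_id) > 0)

  labels <- sprintf("study_%d", 1:6)
  big <- generateCohort(nDonors = 73, ageRange = c(20, 80),
                        studyLabels = labels, seed = 2)
  expect_equal(nrow(big), 73)
  expect_setequal(unique(big$study), labels)
  ## every study keeps both sexes so the meta design stays identifiable
  expect_true(all(tapply(big$sex, big$study,
                         function(s) length(unique(s))) == 2))

  expect_identical(generateCohort(8, c(25, 70), "s", seed = 3),
                   generateCohort(8, c(25, 70), "s", seed = 3))
})

test_that("genome generation places promoters, distal peaks and links", {
  expect_error(generateGenome(peaksPerGene = 1), "distal")
  expect_error(generateGenome(motifDensity = 0), "motifDensity")

  g <- generateGenome(nChrom = 1, genesPerChrom = 10, peaksPerGene = 5,
                      nMotifs = 20, motifDensity = 0.05,
                      nGrammarMotifs = 4, seed = 7)
  expect_equal(nrow(g$genes), 10)
  expect_equal(length(g$peaks), 50)
  expect_equal(dim(g$motifMatrix), c(20, 50))

  ## background occurrence density of non-grammar motifs ~ Bernoulli(0.05)
  bg <- setdiff(rownames(g$motifMatrix),
                c(g$grammar$promoter, g$grammar$distal))
  dens <- mean(as.matrix(g$motifMatrix[bg, ]))
  se <- sqrt(0.05 * 0.95 / (length(bg) * 50))
  expect_lt(abs(dens - 0.05), 3 * se)

  ## both strands represented; every gene has a promoter-overlapping peak
  expect_setequal(unique(g$genes$strand), c("+", "-"))
  for (id in g$genes$gene_id) {
    expect_length(g$genePeaks[[id]]$promoter, 1)
    expect_gte(length(g$genePeaks[[id]]$true_distal), 1)
  }

  ## true links score above the working cutoff, noise links below it
  tl <- g$links$score
  expect_true(all(tl < 0.015 | tl >= 0.1))
})

test_that("promoter windows orient by strand and cover the TSS", {
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      tss = 10000, strand = c("+", "-"),
                      protein_coding = TRUE)
  w <- promoterWindows(genes, upstream = 1500, downstream = 500)
  ## plus strand: [8500, 10500) in 0-based half-open coordinates
  expect_equal(GenomicRanges::start(w["plus"]) - 1, 8500)
  expect_equal(GenomicRanges::end(w["plus"]), 10500)
  ## minus strand: [9500, 11500): upstream lies 5' of the TSS
  expect_equal(GenomicRanges::start(w["minus"]) - 1, 9500)
  expect_equal(GenomicRanges::end(w["minus"]), 11500)
})

test_that("motif occurrences are independent of link structure when no grammar is planted", {
  ## under zero grammar motifs, occurrence in a truly linked distal peak is
  ## independent of occurrence elsewhere: chi-square association tests
  ## should look null across seeds
  pvals <- vapply(1:15, function(s) {
    g <- generateGenome(nChrom = 2, genesPerChrom = 10, peaksPerGene = 4,
                        nMotifs = 10, motifDensity = 0.1,
                        nGrammarMotifs = 0, seed = s)
    linked <- unique(unlist(lapply(g$genePeaks, `[[`, "true_distal")))
    occ <- as.matrix(g$motifMatrix)
    isLinked <- colnames(occ) %in% linked
    counts <- c(sum(occ[, isLinked]), sum(occ[, !isLinked]))
    tot <- c(length(occ[, isLinked]), length(occ[, !isLinked]))
    suppressWarnings(prop.test(counts, tot)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 13)
})

test_that("null truth yields balanced counts and planted QC failures surface", {
  st <- simulateStudy(nDonors = 6, cellsPerSample = 50, nChrom = 3,
                      genesPerChrom = 10, nMotifs = 16, seed = 5)
  cells <- studyCells(st)
  rc <- cells[cells$modality == "RNA", ]
  mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))
  ac <- cells[cells$modality == "ATAC", ]
  male <- ac$sex == "M"
  ratio <- Matrix::rowMeans(mcc[, male]) / Matrix::rowMeans(mcc[, !male])
  ## no planted effects: geometric-mean male/female motif count ratio ~ 1
  ## (donor intercepts with 3 donors per sex leave real spread per motif)
  expect_lt(abs(mean(log(ratio))), 0.35)

  ## planted QC failures are recovered by the filters at about the planted
  ## rate
  truth <- plantedTruth(st)
  frac <- truth$qcFailFrac
  res <- filterRnaCells(rc)
  planted <- sum(!is.na(truth$qcFail$reason[match(rc$cell_id,
                                                  truth$qcFail$cell_id)]))
  expect_equal(nrow(res$dropped), planted)
  expect_lt(abs(nrow(res$dropped) / nrow(rc) - frac), 0.03)
})

test_that("study regeneration under a fixed seed is bit-identical", {
  args <- list(nDonors = 4, cellsPerSample = 30, nChrom = 3,
               genesPerChrom = 8, nMotifs = 12, seed = 77,
               truthArgs = list(nMotifSex = 2))
  a <- do.call(simulateStudy, args)
  b <- do.call(simulateStudy, args)
  expect_identical(rnaCounts(a), rnaCounts(b))
  expect_identical(atacCounts(a), atacCounts(b))
  expect_identical(studyCells(a), studyCells(b))
  expect_identical(plantedTruth(a), plantedTruth(b))
})

test_that("study directories round-trip through write and read", {
  st <- simulateStudy(nDonors = 4, cellsPerSample = 25, nChrom = 3,
                      genesPerChrom = 6, nMotifs = 10, seed = 13)
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  back <- readStudy(dir)
  expect_equal(dim(rnaCounts(back)), dim(rnaCounts(st)))
  expect_equal(as.matrix(rnaCounts(back)), as.matrix(rnaCounts(st)),
               ignore_attr = TRUE)
  expect_identical(names(studyPeaks(back)), names(studyPeaks(st)))
  ## the strong (p < 1e-7) occurrence set reproduces the motif matrix
  expect_equal(as.matrix(motifMatrix(back)) > 0,
               as.matrix(motifMatrix(st)) > 0)
  ## looser cutoffs load strictly more occurrences
  loose <- readStudy(dir, scanPCutoff = 1e-4)
  expect_gt(sum(motifMatrix(loose)), sum(motifMatrix(back)))
})
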