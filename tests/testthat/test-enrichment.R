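test_that("planted sex-associated motifs rise to the top of the battery", {
  st <- fixtureStudy()
  mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))
  ac <- fixtureAtacCells()
  tab <- testMotifCovariate(mcc, ac, "cardiomyocyte", term = "sex")
  truth <- plantedTruth(st)$motifSexBeta
  planted <- names(truth)[truth != 0]
  expect_gt(nrow(tab), 10)
  ## planted motifs dominate the significant calls with correct signs
  hits <- tab[tab$feature %in% planted, ]
  expect_gte(sum(hits$q < 0.1), length(planted) - 1)
  sig <- hits[hits$q < 0.1, ]
  expect_true(all(sign(sig$estimate) == sign(truth[sig$feature])))

  expect_error(testMotifCovariate(mcc, ac, "no_such_type"), "not present")
})

test_that("single-donor cell types are refused", {
  st <- fixtureStudy()
  mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))
  ac <- fixtureAtacCells()
  one <- ac[ac$donor_id == ac$donor_id[1], ]
  expect_error(testMotifCovariate(mcc, one, one$cell_type[1]),
               "fewer than 2 donors")
})

test_that("dummy-variable enrichment finds the type-planted motif", {
  st <- fixtureStudy()
  mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))
  ac <- fixtureAtacCells()
  tab <- testMotifCelltype(mcc, ac, "cardiomyocyte")
  planted <- names(plantedTruth(st)$motifTypePlant)
  row <- tab[tab$feature == planted, ]
  expect_gt(row$estimate, 0)
  expect_lt(row$q, 0.1)
  ## the planted motif carries the strongest enrichment
  expect_equal(tab$feature[which.max(tab$z)], planted)

  expect_error(testMotifCelltype(mcc, ac, "no_such_type"), "not present")
  oneType <- ac; oneType$cell_type <- "A"
  expect_error(testMotifCelltype(mcc, oneType, "A"), ">= 2 cell types")
})

test_that("order of cells does not change dummy-variable enrichment", {
  st <- fixtureStudy()
  mcc <- motifCellCounts(motifMatrix(st), atacCounts(st))
  ac <- fixtureAtacCells()
  sub <- ac[ac$cell_type %in% c("cardiomyocyte", "fibroblast"), ]
  a <- testMotifCelltype(mcc, sub, "cardiomyocyte")
  perm <- sub[rev(seq_len(nrow(sub))), ]
  b <- testMotifCelltype(mcc, perm, "cardiomyocyte")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
})

test_that("differential expression recovers planted sex-regulated genes", {
  st <- fixtureStudy()
  rc <- fixtureRnaCells()
  tab <- deTestGenes(rnaCounts(st), rc, "cardiomyocyte", term = "sex")
  truth <- plantedTruth(st)$geneSexBeta[, "cardiomyocyte"]
  planted <- names(truth)[truth != 0]
  hits <- tab[tab$feature %in% planted, ]
  ## strong planted effects: most recovered at FDR 0.1, significant calls
  ## carry the planted sign, estimates sit near truth
  expect_gte(sum(hits$q < 0.1), length(planted) - 2)
  sig <- hits[hits$q < 0.1, ]
  expect_true(all(sign(sig$estimate) == sign(truth[sig$feature])))
  expect_lt(median(abs(hits$estimate - truth[hits$feature])), 0.4)
})

test_that("meta-analysis design absorbs a planted study shift", {
  st <- simulateStudy(nDonors = 16, cellsPerSample = 50, nChrom = 3,
                      genesPerChrom = 8, nMotifs = 10,
                      studyLabels = c("studyA", "studyB"),
                      truthArgs = list(nGeneAge = 4, geneAgeEffect = 0.03,
                                       studyShiftSd = 0.8),
                      seed = 31)
  rc <- studyCells(st)
  rc <- rc[rc$modality == "RNA", ]
  tab <- deTestGenes(rnaCounts(st), rc, "cardiomyocyte", term = "age",
                     meta = TRUE)
  truth <- plantedTruth(st)$geneAgeBeta[, "cardiomyocyte"]
  planted <- names(truth)[truth != 0]
  hits <- tab[tab$feature %in% planted, ]
  ## ~2SE coverage per event; allow one miss among the planted set
  expect_gte(sum(abs(hits$estimate - truth[hits$feature]) <= 2 * hits$se),
             nrow(hits) - 1)
})

test_that("stage-enrichment comparison flags constructed outliers", {
  set.seed(12)
  adult <- data.frame(feature = sprintf("m%02d", 1:40),
                      estimate = rnorm(40), se = 0.2,
                      q = runif(40, 0, 0.09), stringsAsFactors = FALSE)
  ## identical tables: perfect correlation, no outliers
  cmp <- compareStageEnrichments(adult, adult)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(sum(cmp$table$outlier), 0)

  ## one motif flipped at magnitude 3 stands out
  fetal <- adult
  fetal$estimate[5] <- -3 * sign(adult$estimate[5]) *
    max(abs(adult$estimate))
  cmp2 <- compareStageEnrichments(adult, fetal)
  expect_true(cmp2$table$outlier[5])
  expect_lt(cmp2$pearson_r, 1)

  ## correlation is symmetric in the two tables
  cmp3 <- compareStageEnrichments(fetal, adult)
  expect_equal(cmp2$pearson_r, cmp3$pearson_r, tolerance = 1e-12)

  ## independent tables: correlation near zero
  ind <- adult; ind$estimate <- rnorm(40)
  cmp4 <- compareStageEnrichments(adult, ind)
  expect_lt(abs(cmp4$pearson_r), 3 / sqrt(cmp4$n_included))

  ## only significant-in-either motifs enter unless includeAll is set
  adult2 <- adult; adult2$q <- c(rep(0.05, 10), rep(0.5, 30))
  fetal2 <- adult2; fetal2$q <- 0.5
  cmp5 <- compareStageEnrichments(adult2, fetal2)
  expect_equal(cmp5$n_included, 10)
  cmp6 <- compareStageEnrichments(adult2, fetal2, includeAll = TRUE)
  expect_equal(cmp6$n_included, 40)

  expect_error(compareStageEnrichments(adult,
                                       transform(adult, feature = "x")),
               "no shared motifs")
})
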