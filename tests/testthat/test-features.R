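test_that("feature modes union promoter and linked distal motifs", {
  g <- toyGenome(linkScore = 0.5)
  po <- buildFeatures(g$genes, g$peaks, g$motifMatrix, g$links,
                      mode = "promoter_only")
  pd <- buildFeatures(g$genes, g$peaks, g$motifMatrix, g$links,
                      mode = "promoter_plus_distal")
  expect_equal(as.numeric(featureMatrix(po)["g1", ]), c(1, 0, 0))
  expect_equal(as.numeric(featureMatrix(pd)["g1", ]), c(1, 1, 0))
  expect_equal(featureProvenance(pd)$g1$promoter, "pProm")
  expect_equal(featureProvenance(pd)$g1$distal, "pDistal")

  ## a cutoff above every link score collapses the two modes
  weak <- toyGenome(linkScore = 0.01)
  pd2 <- buildFeatures(weak$genes, weak$peaks, weak$motifMatrix, weak$links,
                       hp = defaultHyperparameters(),
                       mode = "promoter_plus_distal")
  po2 <- buildFeatures(weak$genes, weak$peaks, weak$motifMatrix, weak$links,
                       mode = "promoter_only")
  expect_equal(as.matrix(featureMatrix(pd2)), as.matrix(featureMatrix(po2)))
})

test_that("genes without promoter peaks get all-zero rows and are counted", {
  g <- toyGenome()
  far <- g$genes; far$tss <- 500000  # no peak anywhere near
  f <- buildFeatures(far, g$peaks, g$motifMatrix, g$links)
  expect_true(all(featureMatrix(f)["g1", ] == 0))
  expect_equal(attr(f, "nNoPromoter"), 1L)

  nc <- g$genes; nc$protein_coding <- FALSE
  expect_error(buildFeatures(nc, g$peaks, g$motifMatrix, g$links),
               "protein-coding")
})

test_that("maxDistal keeps the top-scoring linked peaks", {
  genes <- data.frame(gene_id = "g", chrom = "c", tss = 1000, strand = "+",
                      protein_coding = TRUE)
  peaks <- GenomicRanges::GRanges("c", IRanges::IRanges(
    start = c(901, 5001, 9001, 13001), end = c(1400, 5500, 9500, 13500)))
  names(peaks) <- c("prom", "d1", "d2", "d3")
  mm <- Matrix::Matrix(diag(4) > 0, sparse = TRUE,
                       dimnames = list(c("A", "B", "C", "D"), names(peaks)))
  links <- data.frame(peak_a = "prom", peak_b = c("d1", "d2", "d3"),
                      score = c(0.2, 0.5, 0.3))
  hp <- defaultHyperparameters(); hp$maxDistal <- 2
  f <- buildFeatures(genes, peaks, mm, links, hp = hp)
  expect_setequal(featureProvenance(f)$g$distal, c("d2", "d3"))
  expect_equal(as.numeric(featureMatrix(f)["g", ]), c(1, 0, 1, 1))
})

test_that("feature construction equals the per-gene brute-force rescan", {
  set.seed(20)
  hpGrid <- rbind(promoterGrid(), distalGrid())
  for (i in 1:20) {
    g <- generateGenome(nChrom = 2, genesPerChrom = 5,
                        peaksPerGene = sample(3:5, 1), nMotifs = 8,
                        motifDensity = 0.15, nGrammarMotifs = 2, seed = i)
    row <- hpGrid[sample(nrow(hpGrid), 1), ]
    hp <- as.list(row[setdiff(names(row), "mode")])
    f <- buildFeatures(g$genes, g$peaks, g$motifMatrix, g$links, hp = hp,
                       mode = row$mode)
    oracle <- bruteFeatures(g$genes, g$peaks, g$motifMatrix, g$links,
                            .checkHyperparameters(hp), row$mode)
    expect_equal(as.matrix(featureMatrix(f)), oracle, ignore_attr = TRUE)
  }
})

test_that("chromosome splits hit target fractions and stay disjoint", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      chrom = rep(sprintf("c%02d", 1:10), each = 10),
                      stringsAsFactors = FALSE)
  sp <- splitByChromosome(genes, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 1)
  expect_length(sp$test, 1)
  all3 <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all3, unique(genes$chrom))
  expect_equal(anyDuplicated(all3), 0)

  expect_error(splitByChromosome(genes[genes$chrom %in% c("c01", "c02"), ]),
               ">= 3 chromosomes")
  expect_error(splitByChromosome(genes, fractions = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("greedy split tracks the best achievable train fraction", {
  bestTrainDev <- function(counts) {
    ## exhaustive assignment of chromosomes to 3 partitions
    n <- length(counts)
    grid <- expand.grid(rep(list(1:3), n))
    ok <- apply(grid, 1, function(a) all(1:3 %in% a))
    devs <- apply(grid[ok, , drop = FALSE], 1, function(a) {
      abs(sum(counts[a == 1]) / sum(counts) - 0.8)
    })
    min(devs)
  }
  set.seed(99)
  for (i in 1:20) {
    nChrom <- sample(3:7, 1)
    counts <- sample(2:30, nChrom, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(sum(counts))),
      chrom = rep(sprintf("c%02d", seq_len(nChrom)), counts),
      stringsAsFactors = FALSE)
    sp <- splitByChromosome(genes, seed = i)
    trainFrac <- sum(counts[match(sp$train, sprintf("c%02d", 1:nChrom))]) /
      sum(counts)
    expect_lte(abs(trainFrac - 0.8), bestTrainDev(counts) + 0.10 + 1e-9)
  }
})
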