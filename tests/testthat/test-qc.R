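rnaToy <- function() {
  ## six RNA cells: three pass, and each QC rule fails exactly once
  data.frame(
    cell_id = sprintf("c%d", 1:6),
    total_umi = c(5000, 99, 3000, 2500, 100, 800),
    mito_frac = c(0.02, 0.05, 0.2, 0.04, 0.10, 0.08),
    doublet_score = c(0.05, 0.0, 0.1, 0.5, 0.2, 0.15),
    stringsAsFactors = FALSE
  )
}

test_that("RNA filter applies strict-inequality failure thresholds", {
  res <- filterRnaCells(rnaToy())
  expect_equal(nrow(res$kept), 3)
  expect_setequal(res$kept$cell_id, c("c1", "c5", "c6"))
  ## boundary cell (UMI=100, mito=0.10, doublet=0.2) is kept
  expect_true("c5" %in% res$kept$cell_id)
  expect_equal(res$dropped$reasons[res$dropped$cell_id == "c2"], "low_umi")
  expect_equal(res$dropped$reasons[res$dropped$cell_id == "c3"], "high_mito")
  expect_equal(res$dropped$reasons[res$dropped$cell_id == "c4"],
               "high_doublet")

  ## kept and dropped partition the input; the filter is idempotent
  expect_equal(sort(c(res$kept$cell_id, res$dropped$cell_id)),
               sort(rnaToy()$cell_id))
  again <- filterRnaCells(res$kept)
  expect_equal(nrow(again$dropped), 0)
  expect_equal(again$kept$cell_id, res$kept$cell_id)

  expect_error(filterRnaCells(data.frame(cell_id = "x")), "missing")
})

test_that("ATAC filter keeps boundary cells and names failing criteria", {
  cells <- data.frame(
    cell_id = c("b1", "b2", "b3"),
    total_umi = c(1000, 5000, 999),
    frit = c(0.08, 0.07, 0.2),
    frip = c(0.2, 0.3, 0.5),
    doublet_score = c(0.5, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
  res <- filterAtacCells(cells)
  expect_equal(res$kept$cell_id, "b1")  # all four values exactly on boundary
  expect_equal(res$dropped$reasons[res$dropped$cell_id == "b2"], "low_frit")
  expect_equal(res$dropped$reasons[res$dropped$cell_id == "b3"], "low_umi")

  ## a cell failing several rules reports all of them
  multi <- data.frame(cell_id = "m", total_umi = 10, frit = 0.01,
                      frip = 0.1, doublet_score = 0.9)
  expect_equal(filterAtacCells(multi)$dropped$reasons,
               "low_umi,low_frit,low_frip,high_doublet")
})

test_that("planted QC failures are removed at the planted rate", {
  st <- fixtureStudy()
  cells <- studyCells(st)
  ac <- cells[cells$modality == "ATAC", ]
  res <- filterAtacCells(ac)
  frac <- nrow(res$dropped) / nrow(ac)
  expect_lt(abs(frac - plantedTruth(st)$qcFailFrac), 0.03)
})

test_that("kNN transfer recovers labels, confidence and majority rule", {
  ## coincident pure cluster: confidence 1
  rna <- data.frame(cell_id = sprintf("r%d", 1:10),
                    cell_type = "cardiomyocyte",
                    emb1 = rnorm(10, 5, 0.1), emb2 = rnorm(10, 5, 0.1))
  atac <- data.frame(cell_id = "a1", emb1 = 5, emb2 = 5)
  out <- knnLabelTransfer(rna, atac, k = 7)
  expect_equal(out$transferred_label, "cardiomyocyte")
  expect_equal(out$transfer_confidence, 1)

  ## two well-separated clusters: every query hits its own cluster
  set.seed(1)
  rna2 <- data.frame(
    cell_id = sprintf("r%d", 1:100),
    cell_type = rep(c("A", "B"), each = 50),
    emb1 = c(rnorm(50, 0), rnorm(50, 10)), emb2 = rnorm(100))
  atac2 <- data.frame(cell_id = sprintf("a%d", 1:40),
                      emb1 = rnorm(40, 0), emb2 = rnorm(40))
  out2 <- knnLabelTransfer(rna2, atac2, k = 7)
  expect_true(all(out2$transferred_label == "A"))

  ## engineered 4-vs-3 vote: majority wins with confidence 4/7
  rna3 <- data.frame(
    cell_id = sprintf("r%d", 1:7),
    cell_type = c(rep("A", 4), rep("B", 3)),
    emb1 = c(1, 1.1, 1.2, 1.3, 0.5, 0.6, 0.7), emb2 = 0)
  atac3 <- data.frame(cell_id = "a1", emb1 = 0.9, emb2 = 0)
  out3 <- knnLabelTransfer(rna3, atac3, k = 7)
  expect_equal(out3$transferred_label, "A")
  expect_equal(out3$transfer_confidence, 4 / 7)

  expect_error(knnLabelTransfer(rna3[0, ], atac3, k = 7), "empty")
  expect_error(knnLabelTransfer(rna3, atac3, k = 0), "k must be")
  expect_error(knnLabelTransfer(rna3, atac3, k = 100), "exceeds")
})

test_that("label transfer is invariant to reference row order", {
  set.seed(7)
  rna <- data.frame(
    cell_id = sprintf("r%02d", 1:60),
    cell_type = sample(c("A", "B", "C"), 60, replace = TRUE),
    emb1 = rnorm(60), emb2 = rnorm(60))
  atac <- data.frame(cell_id = sprintf("a%d", 1:20),
                     emb1 = rnorm(20), emb2 = rnorm(20))
  a <- knnLabelTransfer(rna, atac, k = 5)
  b <- knnLabelTransfer(rna[sample(60), ], atac, k = 5)
  expect_identical(a$transferred_label, b$transferred_label)
  expect_identical(a$transfer_confidence, b$transfer_confidence)
})

test_that("transfer on the synthetic embedding matches true types", {
  st <- fixtureStudy()
  rna <- fixtureRnaCells()
  atac <- fixtureAtacCells()
  out <- knnLabelTransfer(rna, atac, k = 7)
  expect_gt(mean(out$transferred_label == out$cell_type), 0.98)
})
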