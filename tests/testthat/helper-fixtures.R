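## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

#' A small planted-effect study shared across module tests
fixtureStudy <- function() {
  if (is.null(.fixtureCache$study)) {
    .fixtureCache$study <- simulateStudy(
      nDonors = 6, cellsPerSample = 60, nChrom = 4, genesPerChrom = 12,
      nMotifs = 24, motifDensity = 0.06,
      truthArgs = list(
        nMotifSex = 4, motifSexEffect = 1.0,
        nGeneSex = 6, geneSexEffect = 1.0,
        donorReSd = 0.3,
        propSexBeta = c(cardiomyocyte = 0.8),
        motifTypePlant = c(motif_020 = "cardiomyocyte")
      ),
      seed = 2024)
  }
  .fixtureCache$study
}

#' RNA cells of the fixture with model covariates attached
fixtureRnaCells <- function() {
  cells <- studyCells(fixtureStudy())
  cells[cells$modality == "RNA", , drop = FALSE]
}

fixtureAtacCells <- function() {
  cells <- studyCells(fixtureStudy())
  cells[cells$modality == "ATAC", , drop = FALSE]
}

#' A tiny hand-built genome for feature-construction examples:
#' one gene (plus strand, TSS 10000) with a promoter peak carrying motif A
#' and one linked distal peak carrying motif B, plus an unlinked peak
#' carrying motif C.
toyGenome <- function(linkScore = 0.5) {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                      strand = "+", protein_coding = TRUE,
                      stringsAsFactors = FALSE)
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(9901, 30001, 60001),
                             end = c(10400, 30500, 60500)))
  names(peaks) <- c("pProm", "pDistal", "pFar")
  mm <- Matrix::Matrix(
    matrix(c(1, 0, 0,
             0, 1, 0,
             0, 0, 1), nrow = 3, byrow = TRUE,
           dimnames = list(c("A", "B", "C"), names(peaks))) > 0,
    sparse = TRUE)
  links <- data.frame(peak_a = "pDistal", peak_b = "pProm",
                      score = linkScore, stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks, motifMatrix = mm, links = links)
}

#' Construct a minimal converged FitResult by hand (for transform tests)
manualFit <- function(terms, estimates, ses = rep(0.1, length(terms))) {
  structure(list(
    coefficients = data.frame(term = terms, estimate = estimates, se = ses,
                              stringsAsFactors = FALSE),
    reVariance = 0.1, dispersion = 5, converged = TRUE, pdHess = TRUE,
    loglik = 0, nObs = 10L, nGroups = 5L, family = "betabinom"
  ), class = "FitResult")
}
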