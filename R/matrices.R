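## Core matrix constructions: motif-count x cell matrix and pseudo-bulk
## log2 TPM profiles.

#' Motif-count x cell matrix from motif occurrences and peak accessibility
#'
#' Multiplies the binary motif x peak matrix with the binarized peak x cell
#' accessibility matrix (a peak is accessible in a cell iff its count is
#' > 0), so each entry counts the peaks accessible in a given cell that
#' contain a given motif. Accessibility counts are binarized, not summed:
#' per-site sci-ATAC counts are quasi-binary and the quantity of interest is
#' presence/absence.
#'
#' @param motifMatrix sparse logical motif x peak matrix
#' @param accessibility sparse peak x cell count matrix; rownames must
#'   cover the motif matrix's peak set
#' @return sparse motif x cell integer count matrix
#' @export
motifCellCounts <- function(motifMatrix, accessibility) {
  peakIds <- colnames(motifMatrix)
  missing <- setdiff(peakIds, rownames(accessibility))
  if (length(missing) > 0L) {
    stop("peak ids absent from accessibility matrix: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5),
         call. = FALSE)
  }
  acc <- accessibility[peakIds, , drop = FALSE]
  accBin <- acc
  accBin@x <- as.numeric(accBin@x > 0)
  m <- (motifMatrix * 1) %*% accBin
  as(m, "CsparseMatrix")
}

#' Pseudo-bulk log2(TPM) expression profiles per cell type
#'
#' Pools UMIs over all cells of each type, converts pooled counts to
#' counts-per-million (UMI counts already estimate transcript numbers, so no
#' length normalization applies) and returns log2(TPM + pseudocount).
#'
#' @param rnaCounts sparse gene x cell count matrix
#' @param cellTypes character vector of labels, one per column
#' @param pseudocount added before the log2 (default 1); log2 of zero TPM is
#'   undefined, the pseudocount choice is the caller's
#' @return list with \code{log2tpm} (gene x cell-type matrix),
#'   \code{librarySizes} (pooled UMIs per type) and \code{pseudocount}
#' @export
pseudobulkLog2Tpm <- function(rnaCounts, cellTypes, pseudocount = 1) {
  if (length(cellTypes) != ncol(rnaCounts)) {
    stop("one cell-type label per column is required", call. = FALSE)
  }
  if (anyNA(cellTypes)) stop("every cell must be labeled", call. = FALSE)
  types <- sort(unique(cellTypes))
  pooled <- vapply(types, function(t) {
    Matrix::rowSums(rnaCounts[, cellTypes == t, drop = FALSE])
  }, numeric(nrow(rnaCounts)))
  if (!is.matrix(pooled)) {
    pooled <- matrix(pooled, nrow = nrow(rnaCounts),
                     dimnames = list(rownames(rnaCounts), types))
  }
  lib <- colSums(pooled)
  zero <- lib == 0
  if (any(zero)) {
    warning("cell type(s) with zero total counts excluded: ",
            paste(types[zero], collapse = ", "))
    pooled <- pooled[, !zero, drop = FALSE]
    lib <- lib[!zero]
  }
  tpm <- sweep(pooled, 2, lib, "/") * 1e6
  list(log2tpm = log2(tpm + pseudocount),
       librarySizes = lib,
       pseudocount = pseudocount)
}
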