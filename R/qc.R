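## QC filters and RNA -> ATAC label transfer.
##
## Threshold boundary semantics: the filters state *failure* conditions with
## strict inequalities (UMI < 100, mito% > 10, doublet > 0.2, ...), so cells
## sitting exactly on a boundary are KEPT.

#' Filter RNA cells on UMI, mitochondrial fraction and doublet score
#'
#' A cell is kept iff \code{total_umi >= 100}, \code{mito_frac <= 0.10} and
#' \code{doublet_score <= 0.2}. Dropped cells are annotated with every
#' failing criterion.
#'
#' @param cells data.frame of RNA cell records with fields \code{cell_id},
#'   \code{total_umi}, \code{mito_frac}, \code{doublet_score}
#' @param minUmi,maxMito,maxDoublet thresholds
#' @return list with \code{kept} and \code{dropped} data.frames; dropped
#'   rows gain a \code{reasons} column (comma-separated)
#' @export
filterRnaCells <- function(cells, minUmi = 100, maxMito = 0.10,
                           maxDoublet = 0.2) {
  .requireColumns(cells, c("cell_id", "total_umi", "mito_frac",
                           "doublet_score"), "RNA cell table")
  .qcPartition(cells, list(
    low_umi = cells$total_umi < minUmi,
    high_mito = cells$mito_frac > maxMito,
    high_doublet = cells$doublet_score > maxDoublet
  ))
}

#' Filter ATAC cells on UMI, FRIT, FRIP and doublet likelihood
#'
#' A cell is kept iff \code{total_umi >= 1000}, \code{frit >= 0.08},
#' \code{frip >= 0.2} and \code{doublet_score <= 0.5}.
#'
#' @param cells data.frame of ATAC cell records with fields \code{cell_id},
#'   \code{total_umi}, \code{frit}, \code{frip}, \code{doublet_score}
#' @param minUmi,minFrit,minFrip,maxDoublet thresholds
#' @return list with \code{kept} and \code{dropped} (see
#'   \code{\link{filterRnaCells}})
#' @export
filterAtacCells <- function(cells, minUmi = 1000, minFrit = 0.08,
                            minFrip = 0.2, maxDoublet = 0.5) {
  .requireColumns(cells, c("cell_id", "total_umi", "frit", "frip",
                           "doublet_score"), "ATAC cell table")
  .qcPartition(cells, list(
    low_umi = cells$total_umi < minUmi,
    low_frit = cells$frit < minFrit,
    low_frip = cells$frip < minFrip,
    high_doublet = cells$doublet_score > maxDoublet
  ))
}

#' @noRd
.qcPartition <- function(cells, failures) {
  for (nm in names(failures)) {
    if (anyNA(failures[[nm]])) {
      stop("missing values in QC field underlying criterion '", nm, "'",
           call. = FALSE)
    }
  }
  failMat <- do.call(cbind, failures)
  anyFail <- rowSums(failMat) > 0
  dropped <- cells[anyFail, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    dropped$reasons <- apply(failMat[anyFail, , drop = FALSE], 1, function(f) {
      paste(names(failures)[f], collapse = ",")
    })
  } else {
    dropped$reasons <- character(0)
  }
  list(kept = cells[!anyFail, , drop = FALSE], dropped = dropped)
}

#' Transfer cell-type labels from RNA to ATAC cells by k-nearest neighbors
#'
#' Each ATAC cell receives the majority label among its \code{k} nearest
#' labeled RNA cells in the shared embedding (Euclidean distance). Vote ties
#' are broken by the smaller summed distance of supporting neighbors, then
#' lexicographic label order; distance ties are broken by RNA cell order
#' (row order after sorting by cell_id), making the transfer fully
#' deterministic and invariant to input permutation.
#'
#' @param rnaCells data.frame with \code{cell_id}, \code{cell_type} and
#'   embedding columns
#' @param atacCells data.frame with \code{cell_id} and embedding columns
#' @param k number of neighbors (default 7)
#' @param embeddingCols names of the embedding coordinate columns
#' @return \code{atacCells} with added \code{transferred_label} and
#'   \code{transfer_confidence} (majority vote fraction) columns
#' @export
knnLabelTransfer <- function(rnaCells, atacCells, k = 7,
                             embeddingCols = c("emb1", "emb2")) {
  if (nrow(rnaCells) == 0L) stop("empty RNA reference set", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(rnaCells)) {
    stop("k exceeds the number of RNA reference cells", call. = FALSE)
  }
  .requireColumns(rnaCells, c("cell_id", "cell_type", embeddingCols),
                  "RNA cell table")
  .requireColumns(atacCells, c("cell_id", embeddingCols), "ATAC cell table")

  rnaCells <- rnaCells[order(rnaCells$cell_id), , drop = FALSE]
  ref <- as.matrix(rnaCells[, embeddingCols, drop = FALSE])
  qry <- as.matrix(atacCells[, embeddingCols, drop = FALSE])
  labels <- rnaCells$cell_type

  refSq <- rowSums(ref^2)
  out <- vapply(seq_len(nrow(qry)), function(i) {
    d2 <- refSq - 2 * drop(ref %*% qry[i, ]) + sum(qry[i, ]^2)
    ## stable selection of the k nearest: order by (distance, reference row)
    nn <- order(d2, seq_along(d2))[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sumd <- vapply(top, function(l) sum(sqrt(pmax(d2[nn][labels[nn] == l], 0))),
                     numeric(1))
      top <- top[order(sumd, top)]
    }
    c(top[1], max(votes) / k)
  }, character(2))

  atacCells$transferred_label <- out[1, ]
  atacCells$transfer_confidence <- as.numeric(out[2, ])
  atacCells
}
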