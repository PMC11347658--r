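#' @import methods
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' HeartStudy: a multi-donor single-nucleus RNA + ATAC study
#'
#' Container for everything one study carries: the donor cohort, per-cell
#' metadata for both modalities, gene models, accessible peaks, the binary
#' motif-occurrence matrix, co-accessibility links, and the sparse count
#' matrices. Synthetic studies additionally carry the planted ground truth
#' used by recovery tests.
#'
#' Slots:
#' \describe{
#'   \item{donors}{data.frame: \code{donor_id}, \code{age} (years),
#'     \code{sex} (\code{"F"}/\code{"M"}), \code{study}, \code{sites}
#'     (comma-separated anatomical sites).}
#'   \item{cells}{data.frame of per-cell records, both modalities:
#'     \code{cell_id}, \code{donor_id}, \code{site}, \code{modality},
#'     \code{cell_type}, \code{total_umi}, \code{mito_frac}, \code{frit},
#'     \code{frip}, \code{doublet_score}, \code{emb1}, \code{emb2}.}
#'   \item{genes}{data.frame: \code{gene_id}, \code{chrom}, \code{tss},
#'     \code{strand}, \code{protein_coding}.}
#'   \item{peaks}{\link[GenomicRanges]{GRanges} of accessible peaks, names =
#'     peak ids, 0-based half-open intervals converted to GRanges 1-based
#'     closed at the boundary.}
#'   \item{motifMatrix}{sparse logical motif x peak occurrence matrix
#'     (\code{lgCMatrix}); attribute-free, the scan p-value cutoff used to
#'     binarize is recorded in \code{metadata$scan_p_cutoff}.}
#'   \item{links}{data.frame of co-accessibility links: \code{peak_a},
#'     \code{peak_b}, \code{score}, stored canonically with
#'     \code{peak_a < peak_b}.}
#'   \item{rna}{sparse gene x cell integer count matrix (\code{dgCMatrix}).}
#'   \item{atac}{sparse peak x cell integer count matrix.}
#'   \item{truth}{list of planted effects (see \code{\link{plantedEffects}})
#'     or NULL for real data.}
#'   \item{metadata}{free-form list (seed, generator parameters, cutoffs).}
#' }
#'
#' @aliases HeartStudy-class
#' @export
setClass("HeartStudy",
  slots = c(
    donors = "data.frame",
    cells = "data.frame",
    genes = "data.frame",
    peaks = "GRanges",
    motifMatrix = "Matrix",
    links = "data.frame",
    rna = "Matrix",
    atac = "Matrix",
    truth = "ListOrNULL",
    metadata = "list"
  )
)

setValidity("HeartStudy", function(object) {
  msg <- character()
  d <- object@donors
  if (anyDuplicated(d$donor_id)) msg <- c(msg, "donor_id values must be unique")
  if (any(!is.finite(d$age)) || any(d$age <= 0)) {
    msg <- c(msg, "donor ages must be positive and finite")
  }
  cells <- object@cells
  if (nrow(cells) > 0L) {
    if (!all(cells$donor_id %in% d$donor_id)) {
      msg <- c(msg, "every cell must reference an existing donor")
    }
    if (anyDuplicated(cells$cell_id)) msg <- c(msg, "cell_id values must be unique")
  }
  if (ncol(object@motifMatrix) != length(object@peaks)) {
    msg <- c(msg, "motifMatrix columns must match peaks")
  }
  if (nrow(object@atac) != length(object@peaks)) {
    msg <- c(msg, "atac rows must match peaks")
  }
  if (nrow(object@rna) != nrow(object@genes)) {
    msg <- c(msg, "rna rows must match genes")
  }
  rnaCells <- cells$cell_id[cells$modality == "RNA"]
  atacCells <- cells$cell_id[cells$modality == "ATAC"]
  if (!identical(colnames(object@rna), rnaCells)) {
    msg <- c(msg, "rna columns must match RNA cells in order")
  }
  if (!identical(colnames(object@atac), atacCells)) {
    msg <- c(msg, "atac columns must match ATAC cells in order")
  }
  if (length(msg) > 0L) msg else TRUE
})

#' MotifFeatures: binary gene x motif design matrix for expression models
#'
#' Built by \code{\link{buildFeatures}} from promoter peaks alone
#' (\code{mode = "promoter_only"}) or promoters plus co-accessibility-linked
#' distal sites (\code{mode = "promoter_plus_distal"}). Per-gene provenance
#' (which peaks contributed) is retained so the matrix can be reproduced.
#'
#' @aliases MotifFeatures-class
#' @export
setClass("MotifFeatures",
  slots = c(
    matrix = "Matrix",
    mode = "character",
    hyperparameters = "list",
    provenance = "list"
  )
)

setValidity("MotifFeatures", function(object) {
  msg <- character()
  if (!object@mode %in% c("promoter_only", "promoter_plus_distal")) {
    msg <- c(msg, "mode must be 'promoter_only' or 'promoter_plus_distal'")
  }
  vals <- unique(object@matrix@x)
  if (length(vals) > 0L && !all(vals %in% c(0, 1, TRUE))) {
    msg <- c(msg, "feature matrix must be binary")
  }
  if (length(object@provenance) != nrow(object@matrix)) {
    msg <- c(msg, "provenance must have one entry per gene")
  }
  if (length(msg) > 0L) msg else TRUE
})

#' ExpressionModel: a fitted penalized motif-grammar model for one cell type
#'
#' @aliases ExpressionModel-class
#' @export
setClass("ExpressionModel",
  slots = c(
    cellType = "character",
    intercept = "numeric",
    coefficients = "numeric",
    alpha = "numeric",
    lambda = "numeric",
    mode = "character",
    r2 = "numeric"
  )
)

setValidity("ExpressionModel", function(object) {
  if (is.null(names(object@coefficients))) {
    "coefficients must be named by motif"
  } else TRUE
})

#' @describeIn HeartStudy donor table accessor
#' @param x a \code{HeartStudy}
#' @export
studyDonors <- function(x) x@donors

#' @describeIn HeartStudy cell metadata accessor
#' @export
studyCells <- function(x) x@cells

#' @describeIn HeartStudy gene model accessor
#' @export
studyGenes <- function(x) x@genes

#' @describeIn HeartStudy peak GRanges accessor
#' @export
studyPeaks <- function(x) x@peaks

#' @describeIn HeartStudy motif x peak binary occurrence matrix
#' @export
motifMatrix <- function(x) x@motifMatrix

#' @describeIn HeartStudy co-accessibility link table
#' @export
coaccessLinks <- function(x) x@links

#' @describeIn HeartStudy gene x cell sparse RNA counts
#' @export
rnaCounts <- function(x) x@rna

#' @describeIn HeartStudy peak x cell sparse ATAC counts
#' @export
atacCounts <- function(x) x@atac

#' @describeIn HeartStudy planted ground-truth list (synthetic studies)
#' @export
plantedTruth <- function(x) x@truth

#' @describeIn HeartStudy metadata list
#' @export
studyMetadata <- function(x) x@metadata

setMethod("show", "HeartStudy", function(object) {
  cells <- object@cells
  cat("HeartStudy:",
      nrow(object@donors), "donors,",
      sum(cells$modality == "RNA"), "RNA cells,",
      sum(cells$modality == "ATAC"), "ATAC cells\n")
  cat("  genes:", nrow(object@genes),
      " peaks:", length(object@peaks),
      " motifs:", nrow(object@motifMatrix),
      " links:", nrow(object@links), "\n")
  if (!is.null(object@truth)) {
    cat("  synthetic study with planted truth (seed ",
        object@metadata$seed %||% NA, ")\n", sep = "")
  }
})

setMethod("show", "MotifFeatures", function(object) {
  cat("MotifFeatures [", object@mode, "]: ",
      nrow(object@matrix), " genes x ", ncol(object@matrix), " motifs, ",
      "density ", signif(Matrix::mean(object@matrix), 3), "\n", sep = "")
})

setMethod("show", "ExpressionModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("ExpressionModel for", object@cellType, "[", object@mode, "]:",
      nz, "nonzero of", length(object@coefficients), "motif coefficients\n")
  cat("  alpha =", object@alpha, " lambda =", signif(object@lambda, 4), "\n")
  if (length(object@r2) > 0L) {
    cat("  R2:", paste(names(object@r2), signif(object@r2, 3),
                       sep = "=", collapse = "  "), "\n")
  }
})

#' @describeIn MotifFeatures binary gene x motif matrix accessor
#' @param x a \code{MotifFeatures}
#' @export
featureMatrix <- function(x) x@matrix

#' @describeIn MotifFeatures feature construction mode
#' @export
featureMode <- function(x) x@mode

#' @describeIn MotifFeatures hyperparameters used for construction
#' @export
featureHyperparameters <- function(x) x@hyperparameters

#' @describeIn MotifFeatures per-gene peak provenance
#' @export
featureProvenance <- function(x) x@provenance

#' @describeIn ExpressionModel named motif coefficient vector
#' @param object an \code{ExpressionModel}
#' @export
modelCoefficients <- function(object) object@coefficients

#' @describeIn ExpressionModel named R-squared vector (train/validation/test)
#' @export
modelR2 <- function(object) object@r2

`%||%` <- function(a, b) if (is.null(a)) b else a
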