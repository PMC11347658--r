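## Motif-by-covariate tests, dummy-variable cell-type enrichment,
## per-cell-type differential expression, and the fetal-vs-adult
## enrichment comparison.
##
## Every battery fits one mixed model per feature through the shared engine,
## then applies Wald z-tests with BH correction within the (cell type x
## term x analysis) family, because results are reported per cell type.
## Features enter testing only if nonzero in >= 1% of the cells analyzed
## (near-absent features carry no information and destabilize fits).

#' @noRd
.cellCovariates <- function(cells) {
  cells$log_depth <- log10(pmax(cells$total_umi, 1))
  cells
}

#' @noRd
.inclusionFilter <- function(counts, minFrac = 0.01) {
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  rownames(counts)[frac >= minFrac]
}

#' @noRd
.featureBattery <- function(counts, cells, fixedTerms, term, fdr,
                            minFrac = 0.01) {
  keep <- .inclusionFilter(counts, minFrac)
  fits <- lapply(keep, function(f) {
    fitNbGlmm(as.numeric(counts[f, ]), cells, fixedTerms = fixedTerms)
  })
  names(fits) <- keep
  waldBh(fits, term, fdr)
}

#' Test motif accessibility against a donor covariate within one cell type
#'
#' One negative-binomial mixed model per motif over all cells of the given
#' type: fixed effects of age, sex, anatomical site and log10 UMI, donor
#' random intercept; Wald z and BH across motifs.
#'
#' @param motifCounts motif x cell count matrix
#'   (\code{\link{motifCellCounts}})
#' @param cells cell metadata aligned with the matrix columns (fields
#'   donor_id, site, age, sex, cell_type, total_umi)
#' @param cellType cell type whose cells are analyzed
#' @param term tested covariate, \code{"age"} or \code{"sex"}
#' @param fdr BH significance threshold (default 0.1)
#' @return a test table (see \code{\link{waldBh}})
#' @export
testMotifCovariate <- function(motifCounts, cells, cellType,
                               term = c("age", "sex"), fdr = 0.1) {
  term <- match.arg(term)
  sel <- cells$cell_type == cellType
  if (!any(sel)) stop("cell type not present: ", cellType, call. = FALSE)
  cells <- .cellCovariates(cells[sel, , drop = FALSE])
  if (length(unique(cells$donor_id)) < 2) {
    stop("cell type '", cellType, "' has fewer than 2 donors", call. = FALSE)
  }
  counts <- motifCounts[, cells$cell_id, drop = FALSE]
  .featureBattery(counts, cells,
                  fixedTerms = c("age", "sex", "site", "log_depth"),
                  term = term, fdr = fdr)
}

#' Cell-type-specific motif enrichment via a dummy variable
#'
#' All cells are analyzed at once with a dummy covariate valued 1 for cells
#' of the target type and 0 otherwise; the dummy coefficient is the
#' enrichment of each motif in the target type's accessible peaks, over and
#' above age, sex, site, depth and donor effects.
#'
#' @inheritParams testMotifCovariate
#' @param targetType the cell type whose enrichment is tested
#' @return a test table for the dummy term
#' @export
testMotifCelltype <- function(motifCounts, cells, targetType, fdr = 0.1) {
  if (length(unique(cells$cell_type)) < 2) {
    stop("need >= 2 cell types for a dummy-variable enrichment",
         call. = FALSE)
  }
  if (!any(cells$cell_type == targetType)) {
    stop("cell type not present: ", targetType, call. = FALSE)
  }
  cells <- .cellCovariates(cells)
  cells$type_dummy <- as.numeric(cells$cell_type == targetType)
  counts <- motifCounts[, cells$cell_id, drop = FALSE]
  .featureBattery(counts, cells,
                  fixedTerms = c("type_dummy", "age", "sex", "site",
                                 "log_depth"),
                  term = "type_dummy", fdr = fdr)
}

#' Differential gene expression within one cell type
#'
#' One NB mixed model per gene over all cells of the type. The discovery
#' design uses age, sex, site and log10 UMI as fixed effects with a donor
#' random intercept; \code{meta = TRUE} adds a study (data source) fixed
#' effect for multi-study cohorts.
#'
#' @param rnaCounts gene x cell count matrix
#' @param cells cell metadata aligned with the columns
#' @param cellType cell type analyzed
#' @param term tested covariate
#' @param meta include a study fixed effect (meta-analysis design)
#' @param fdr BH threshold
#' @return a test table
#' @export
deTestGenes <- function(rnaCounts, cells, cellType, term = c("age", "sex"),
                        meta = FALSE, fdr = 0.1) {
  term <- match.arg(term)
  sel <- cells$cell_type == cellType
  if (!any(sel)) stop("cell type not present: ", cellType, call. = FALSE)
  cells <- .cellCovariates(cells[sel, , drop = FALSE])
  if (length(unique(cells$donor_id)) < 2) {
    stop("cell type '", cellType, "' has fewer than 2 donors", call. = FALSE)
  }
  fixedTerms <- c("age", "sex", "site", "log_depth")
  if (meta) fixedTerms <- c(fixedTerms, "study")
  counts <- rnaCounts[, cells$cell_id, drop = FALSE]
  .featureBattery(counts, cells, fixedTerms = fixedTerms, term = term,
                  fdr = fdr)
}

#' Compare stage-specific (e.g. adult vs fetal) motif enrichment tables
#'
#' Restricts to motifs significant in either table at the FDR cutoff,
#' correlates the two estimate vectors (Pearson), and flags outliers by
#' standardized orthogonal-regression residual — a reproducible stand-in
#' for the qualitative visual selection the comparison is usually made by.
#'
#' @param adult,fetal test tables sharing a motif namespace (columns
#'   feature, estimate, q)
#' @param fdr inclusion cutoff on q (default 0.1)
#' @param outlierZ standardized orthogonal residual above which a motif is
#'   flagged (default 2.5)
#' @param includeAll if TRUE, correlate over all shared motifs instead of
#'   the significant-in-either subset
#' @return list with the joined table (estimates, inclusion and outlier
#'   flags, residuals), \code{pearson_r} and \code{n_included}
#' @export
compareStageEnrichments <- function(adult, fetal, fdr = 0.1, outlierZ = 2.5,
                                    includeAll = FALSE) {
  shared <- intersect(adult$feature, fetal$feature)
  if (length(shared) == 0L) stop("no shared motifs", call. = FALSE)
  a <- adult[match(shared, adult$feature), ]
  f <- fetal[match(shared, fetal$feature), ]
  included <- if (includeAll) rep(TRUE, length(shared)) else
    (a$q < fdr) | (f$q < fdr)
  if (sum(included) < 3) {
    stop("fewer than 3 motifs significant in either table at FDR ", fdr,
         call. = FALSE)
  }
  x <- a$estimate[included]
  y <- f$estimate[included]
  r <- cor(x, y)

  ## orthogonal (total least squares) residuals, standardized
  cx <- x - mean(x); cy <- y - mean(y)
  sv <- svd(cbind(cx, cy))
  dir <- sv$v[, 1]
  resid <- cx * (-dir[2]) + cy * dir[1]
  sdr <- sd(resid)
  ## identical tables leave numerically-zero residuals: nothing to flag
  zres <- if (sdr <= 1e-10 * max(sd(x), sd(y), 1)) rep(0, length(resid))
          else resid / sdr

  tab <- data.frame(
    feature = shared,
    adult_estimate = a$estimate,
    adult_se = if ("se" %in% names(a)) a$se else NA_real_,
    adult_q = a$q,
    fetal_estimate = f$estimate, fetal_q = f$q,
    included = included,
    residual = NA_real_, outlier = FALSE,
    stringsAsFactors = FALSE
  )
  tab$residual[included] <- zres
  tab$outlier[included] <- abs(zres) > outlierZ
  list(table = tab, pearson_r = r, n_included = sum(included),
       fdr = fdr, outlierZ = outlierZ)
}
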