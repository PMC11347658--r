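## Elastic net models of cell-type pseudo-bulk expression from binary
## motif features: penalty selection by internal cross-validation on
## training genes, hyperparameter search scored on validation genes, and
## the final test-set evaluation / all-data coefficient report.

#' @noRd
.r2 <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - pred)^2) / sst
}

#' Fit an elastic net motif-grammar model for one cell type
#'
#' Mixing (alpha) and strength (lambda) are chosen by
#' \code{cvFolds}-fold cross-validation on the training genes only; the
#' model is then refit on the full training partition at the chosen
#' penalties. Binary features are not standardized and the intercept is
#' unpenalized. R-squared (1 - SS_res / SS_tot) is reported for every
#' partition with genes.
#'
#' @param features a \link{MotifFeatures}
#' @param expression named numeric vector (gene -> log2 TPM) or a gene x
#'   cell-type matrix together with \code{cellType}
#' @param genes gene table (gene_id, chrom) for partition lookup
#' @param split output of \code{\link{splitByChromosome}}
#' @param cellType column of \code{expression} when it is a matrix; also
#'   recorded on the model
#' @param cvFolds internal CV folds (default 10)
#' @param alphaGrid elastic net mixing values searched
#' @param trainPartitions partitions pooled for fitting (default train;
#'   the test-stage protocol pools train + validation)
#' @param seed seed for the CV fold assignment
#' @return an \link{ExpressionModel}
#' @export
fitElasticNet <- function(features, expression, genes, split,
                          cellType = NA_character_, cvFolds = 10,
                          alphaGrid = c(0.05, 0.25, 0.5, 0.75, 0.95),
                          trainPartitions = "train", seed = 1) {
  x <- featureMatrix(features)
  if (is.matrix(expression) || inherits(expression, "Matrix")) {
    if (is.na(cellType) || !cellType %in% colnames(expression)) {
      stop("cellType must name a column of the expression matrix",
           call. = FALSE)
    }
    expression <- setNames(as.numeric(expression[, cellType]),
                           rownames(expression))
  }
  shared <- intersect(rownames(x), names(expression))
  x <- x[shared, , drop = FALSE]
  y <- expression[shared]
  genes <- genes[match(shared, genes$gene_id), , drop = FALSE]

  trainChroms <- unlist(split[trainPartitions], use.names = FALSE)
  trainIdx <- which(genes$chrom %in% trainChroms)
  if (length(trainIdx) < 20) {
    stop("fewer than 20 training genes", call. = FALSE)
  }
  yTrain <- y[trainIdx]
  if (sd(yTrain) == 0) stop("zero-variance response", call. = FALSE)
  xTrain <- x[trainIdx, , drop = FALSE]

  withr::local_seed(childSeed(seed, "cvfolds"))
  foldid <- sample(rep(seq_len(cvFolds), length.out = length(trainIdx)))
  best <- NULL
  for (a in alphaGrid) {
    cv <- glmnet::cv.glmnet(xTrain, yTrain, alpha = a, foldid = foldid,
                            standardize = FALSE)
    i <- which(cv$lambda == cv$lambda.min)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(alpha = a, lambda = cv$lambda.min, cvm = cv$cvm[i])
    }
  }
  fit <- glmnet::glmnet(xTrain, yTrain, alpha = best$alpha,
                        lambda = best$lambda, standardize = FALSE)
  beta <- setNames(as.numeric(fit$beta), rownames(fit$beta))
  intercept <- as.numeric(fit$a0)

  pred <- as.numeric(x %*% beta) + intercept
  r2 <- c(train = .r2(y[trainIdx], pred[trainIdx]))
  for (p in c("validation", "test")) {
    idx <- which(genes$chrom %in% split[[p]])
    if (length(idx) > 1) r2[[p]] <- .r2(y[idx], pred[idx])
  }
  new("ExpressionModel", cellType = as.character(cellType),
      intercept = intercept, coefficients = beta,
      alpha = best$alpha, lambda = best$lambda,
      mode = featureMode(features), r2 = r2)
}

#' The promoter-stage and distal-stage hyperparameter grids
#'
#' \code{promoterGrid()} crosses promoter windows \{1000/200, 1500/500,
#' 5000/2000\} with motif cutoffs \{1e-4, 1e-5, 1e-6\} (9 points, mode
#' promoter_only). \code{distalGrid()} holds the promoter at 1500/500 and
#' crosses co-accessibility cutoffs \{0.015, 0.035, 0.05\}, max distal
#' sites \{5, 10, 20\}, distal windows \{600, 1000\} and motif cutoffs
#' \{1e-4, 1e-5, 1e-6\} (54 points, mode promoter_plus_distal).
#'
#' @return data.frame of hyperparameter combinations with a \code{mode}
#'   column
#' @export
promoterGrid <- function() {
  g <- expand.grid(
    window = c("1000/200", "1500/500", "5000/2000"),
    motifPCutoff = c(1e-4, 1e-5, 1e-6),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ud <- do.call(rbind, strsplit(g$window, "/", fixed = TRUE))
  data.frame(promoterUpstream = as.numeric(ud[, 1]),
             promoterDownstream = as.numeric(ud[, 2]),
             motifPCutoff = g$motifPCutoff,
             coaccCutoff = 1, maxDistal = 0,
             distalWindow = 1000,
             mode = "promoter_only", stringsAsFactors = FALSE)
}

#' @rdname promoterGrid
#' @export
distalGrid <- function() {
  g <- expand.grid(
    coaccCutoff = c(0.015, 0.035, 0.05),
    maxDistal = c(5, 10, 20),
    distalWindow = c(600, 1000),
    motifPCutoff = c(1e-4, 1e-5, 1e-6),
    KEEP.OUT.ATTRS = FALSE)
  data.frame(promoterUpstream = 1500, promoterDownstream = 500,
             motifPCutoff = g$motifPCutoff, coaccCutoff = g$coaccCutoff,
             maxDistal = g$maxDistal, distalWindow = g$distalWindow,
             mode = "promoter_plus_distal", stringsAsFactors = FALSE)
}

#' Hyperparameter search scored on the validation partition
#'
#' For every grid row, features are built (by \code{buildFn} or directly
#' from the supplied genome pieces), one model per cell type is trained on
#' the training genes, and the validation R-squared is averaged
#' (unweighted) across cell types. The best row maximizes that mean.
#'
#' @param grid data.frame of hyperparameter rows with a \code{mode} column
#'   (see \code{\link{promoterGrid}}, \code{\link{distalGrid}})
#' @param buildFn function(hp, mode) -> \link{MotifFeatures}; use
#'   \code{\link{featureBuilder}} for the common case
#' @param expression gene x cell-type log2 TPM matrix
#' @param genes gene table
#' @param split chromosome split
#' @param cellTypes columns of \code{expression} to score (default all)
#' @param cvFolds,seed forwarded to \code{\link{fitElasticNet}}
#' @return list with \code{table} (the grid plus per-row mean validation
#'   R-squared and failure flags) and \code{best} (hyperparameter list of
#'   the winning row)
#' @export
hyperparameterSearch <- function(grid, buildFn, expression, genes, split,
                                 cellTypes = colnames(expression),
                                 cvFolds = 10, seed = 1) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  hpCols <- setdiff(names(grid), "mode")
  meanR2 <- rep(NA_real_, nrow(grid))
  failed <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- as.list(grid[i, hpCols])
    mode <- grid$mode[i]
    res <- tryCatch({
      feats <- buildFn(hp, mode)
      r2s <- vapply(cellTypes, function(ct) {
        m <- fitElasticNet(feats, expression, genes, split, cellType = ct,
                           cvFolds = cvFolds, seed = seed)
        modelR2(m)[["validation"]]
      }, numeric(1))
      mean(r2s)
    }, error = function(e) NA_real_)
    if (is.na(res)) failed[i] <- TRUE else meanR2[i] <- res
  }
  tab <- cbind(grid, mean_validation_r2 = meanR2, failed = failed)
  if (all(failed)) stop("every grid point failed", call. = FALSE)
  bestIdx <- which.max(meanR2)
  list(table = tab, best = as.list(grid[bestIdx, hpCols]),
       bestMode = grid$mode[bestIdx], bestIdx = bestIdx)
}

#' Convenience feature builder closure over one genome
#'
#' @param genes,peaks,motifMatrix,links genome pieces as in
#'   \code{\link{buildFeatures}}
#' @return function(hp, mode) -> \link{MotifFeatures}
#' @export
featureBuilder <- function(genes, peaks, motifMatrix, links) {
  function(hp, mode) buildFeatures(genes, peaks, motifMatrix, links,
                                   hp = hp, mode = mode)
}

#' Final test-set evaluation and all-data coefficient report
#'
#' With hyperparameters fixed (before ever touching the test partition),
#' fits per cell type and mode: (i) a test-stage model with penalties set
#' by internal CV on pooled train + validation genes, evaluated on the
#' test partition; (ii) a final model trained on all genes whose
#' coefficients are the reported motif grammar. Optionally relates test
#' R-squared to cell-type abundance.
#'
#' @param hp hyperparameter list (the selected working point)
#' @param buildFn function(hp, mode) -> \link{MotifFeatures}
#' @param expression gene x cell-type log2 TPM matrix
#' @param genes gene table
#' @param split chromosome split
#' @param cellTypes cell types to model (default all columns)
#' @param abundance optional named vector of cells per type for the
#'   accuracy-vs-abundance report
#' @param cvFolds,seed forwarded to \code{\link{fitElasticNet}}
#' @return list with \code{testR2} (data.frame cell_type x mode),
#'   \code{finalModels} (list mode -> cell type -> \link{ExpressionModel}),
#'   \code{coefficients} (long data.frame of final promoter_plus_distal
#'   coefficients) and, when abundance is given, \code{abundanceR2} with
#'   its Spearman rank correlation
#' @export
finalFitAndReport <- function(hp, buildFn, expression, genes, split,
                              cellTypes = colnames(expression),
                              abundance = NULL, cvFolds = 10, seed = 1) {
  modes <- c("promoter_only", "promoter_plus_distal")
  feats <- lapply(setNames(modes, modes), function(m) buildFn(hp, m))

  testR2 <- do.call(rbind, lapply(cellTypes, function(ct) {
    r2s <- vapply(modes, function(m) {
      fit <- fitElasticNet(feats[[m]], expression, genes, split,
                           cellType = ct, cvFolds = cvFolds,
                           trainPartitions = c("train", "validation"),
                           seed = seed)
      modelR2(fit)[["test"]]
    }, numeric(1))
    data.frame(cell_type = ct, promoter_only = r2s[1],
               promoter_plus_distal = r2s[2], stringsAsFactors = FALSE)
  }))

  allSplit <- list(train = unique(genes$chrom), validation = character(0),
                   test = character(0))
  finalModels <- lapply(setNames(modes, modes), function(m) {
    fits <- lapply(cellTypes, function(ct) {
      fitElasticNet(feats[[m]], expression, genes, allSplit, cellType = ct,
                    cvFolds = cvFolds, seed = seed)
    })
    names(fits) <- cellTypes
    fits
  })

  coefTab <- do.call(rbind, lapply(cellTypes, function(ct) {
    b <- modelCoefficients(finalModels$promoter_plus_distal[[ct]])
    data.frame(cell_type = ct, motif = names(b), coefficient = as.numeric(b),
               stringsAsFactors = FALSE)
  }))

  out <- list(testR2 = testR2, finalModels = finalModels,
              coefficients = coefTab, hyperparameters = hp)
  if (!is.null(abundance)) {
    ab <- abundance[testR2$cell_type]
    out$abundanceR2 <- data.frame(
      cell_type = testR2$cell_type, abundance = as.numeric(ab),
      test_r2 = testR2$promoter_plus_distal, stringsAsFactors = FALSE)
    out$abundanceCor <- cor(out$abundanceR2$abundance,
                            out$abundanceR2$test_r2, method = "spearman")
  }
  out
}
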