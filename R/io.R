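## Readers/writers for the on-disk formats the pipeline touches.
##
## Coordinate convention: 0-based half-open (BED) on disk and in the
## `start`/`end` columns of exported tables; GRanges objects built from them
## use the usual 1-based closed convention (start+1), converted back on
## write. A single conversion point avoids off-by-one drift.

#' Read a BED3/BED4 file of peaks
#'
#' @param path path to a tab-separated BED file (no header). Column 4, when
#'   present, supplies peak ids; otherwise ids are generated as
#'   \code{chrom:start-end} from the 0-based half-open coordinates.
#' @return a \link[GenomicRanges]{GRanges} sorted by (chrom, start), with
#'   unique names as peak ids.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty BED file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L)) {
    stop(sprintf("%s line %d: fewer than 3 tab-separated columns",
                 path, which(n < 3L)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: non-numeric coordinates", path, bad[1]),
         call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: invalid interval (start %s, end %s)",
                 path, bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  ids <- ifelse(n >= 4L, vapply(fields, `[`, character(1), 4L),
                sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)))
  if (anyDuplicated(ids)) {
    stop("duplicate peak ids in ", path, call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end))
  names(gr) <- ids
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

#' Write peaks as BED4
#'
#' @param peaks a named GRanges
#' @param path output path
#' @export
writeBed <- function(peaks, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = names(peaks)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket sparse count matrix with row/column id sidecars
#'
#' @param matrixPath path to a coordinate-format .mtx file
#' @param rowsPath,colsPath one-id-per-line text files naming rows/columns
#' @return a sparse \code{dgCMatrix} with dimnames
#' @export
readMtx <- function(matrixPath, rowsPath, colsPath) {
  m <- Matrix::readMM(matrixPath)
  rows <- readLines(rowsPath)
  cols <- readLines(colsPath)
  rows <- rows[nzchar(rows)]
  cols <- cols[nzchar(cols)]
  if (nrow(m) != length(rows)) {
    stop(sprintf("matrix has %d rows but %s lists %d ids",
                 nrow(m), rowsPath, length(rows)), call. = FALSE)
  }
  if (ncol(m) != length(cols)) {
    stop(sprintf("matrix has %d columns but %s lists %d ids",
                 ncol(m), colsPath, length(cols)), call. = FALSE)
  }
  if (anyDuplicated(rows) || anyDuplicated(cols)) {
    stop("row/column ids must be unique", call. = FALSE)
  }
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  if (any(m@x < 0)) stop("negative entries in count matrix", call. = FALSE)
  dimnames(m) <- list(rows, cols)
  m
}

#' Write a sparse matrix as MatrixMarket plus id sidecars
#'
#' @param m a sparse matrix with dimnames
#' @param matrixPath,rowsPath,colsPath output paths
#' @export
writeMtx <- function(m, matrixPath, rowsPath, colsPath) {
  dir.create(dirname(matrixPath), showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(m, "CsparseMatrix"), matrixPath)
  writeLines(rownames(m), rowsPath)
  writeLines(colnames(m), colsPath)
  invisible(matrixPath)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then one or more gene ids, all
#' tab-separated. Duplicate genes within a set are collapsed; empty sets and
#' duplicate set names are errors.
#'
#' @param path path to a .gmt file
#' @return a named list of character vectors of gene ids
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("%s line %d: GMT lines need name, description and >=1 gene",
                 path, short[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names in ", path, ": ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Read FIMO/MOODS-style motif occurrence calls and binarize at a cutoff
#'
#' The scan file is a tab-separated table with header columns \code{motif},
#' \code{peak}, \code{score}, \code{p_value}: one row per motif occurrence.
#' A single scan file serves every analysis because binarization happens at
#' load time: the enrichment analyses use a 1e-7 cutoff while the expression
#' models sweep 1e-4..1e-6.
#'
#' @param path scan file path
#' @param peakIds full universe of peak ids (matrix columns); occurrences
#'   naming unknown peaks are an error
#' @param motifIds optional full motif universe; defaults to motifs observed
#' @param pCutoff occurrences with \code{p_value <= pCutoff} set the entry
#' @return sparse logical motif x peak matrix, cutoff recorded in
#'   \code{attr(, "scan_p_cutoff")}
#' @export
readMotifOccurrences <- function(path, peakIds, motifIds = NULL,
                                 pCutoff = 1e-7) {
  .assertScalarNumber(pCutoff, "pCutoff", 0, 1)
  occ <- readTsv(path)
  .requireColumns(occ, c("motif", "peak", "score", "p_value"),
                  "motif occurrence file")
  unknown <- setdiff(occ$peak, peakIds)
  if (length(unknown) > 0L) {
    stop("occurrences reference unknown peak ids: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(motifIds)) motifIds <- sort(unique(occ$motif))
  keep <- occ$p_value <= pCutoff & occ$motif %in% motifIds
  occ <- occ[keep, , drop = FALSE]
  m <- Matrix::sparseMatrix(
    i = match(occ$motif, motifIds),
    j = match(occ$peak, peakIds),
    x = TRUE,
    dims = c(length(motifIds), length(peakIds)),
    dimnames = list(motifIds, peakIds)
  )
  attr(m, "scan_p_cutoff") <- pCutoff
  m
}

#' Read co-accessibility links
#'
#' @param path TSV with columns \code{peak_a}, \code{peak_b}, \code{score}
#' @return data.frame with links stored canonically (\code{peak_a < peak_b});
#'   duplicate pairs collapsed to their maximum score
#' @export
readLinks <- function(path) {
  df <- readTsv(path)
  .requireColumns(df, c("peak_a", "peak_b", "score"), "link file")
  if (any(abs(df$score) > 1)) {
    stop("co-accessibility scores must lie in [-1, 1]", call. = FALSE)
  }
  canonicalLinks(df)
}

#' @noRd
canonicalLinks <- function(df) {
  a <- pmin(df$peak_a, df$peak_b)
  b <- pmax(df$peak_a, df$peak_b)
  out <- data.frame(peak_a = a, peak_b = b, score = df$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$peak_a, out$peak_b, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("peak_a", "peak_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a minimal gene-model table
#'
#' @param path TSV with columns \code{gene_id}, \code{chrom}, \code{tss}
#'   (0-based position), \code{strand} (+/-), \code{protein_coding}
#'   (TRUE/FALSE)
#' @return validated data.frame
#' @export
readGenes <- function(path) {
  df <- readTsv(path)
  .requireColumns(df, c("gene_id", "chrom", "tss", "strand", "protein_coding"),
                  "gene table")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  df$protein_coding <- as.logical(df$protein_coding)
  df
}

#' Read per-cell metadata
#'
#' @param path TSV of cell records
#' @return validated data.frame
#' @export
readCells <- function(path) {
  df <- readTsv(path)
  .requireColumns(df, c("cell_id", "donor_id", "site", "modality",
                        "cell_type", "total_umi", "doublet_score"),
                  "cell table")
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id", call. = FALSE)
  df
}

#' Write / read a test table (TSV round trip)
#'
#' Result tables round-trip bit-identically: numeric columns are printed with
#' full precision (\code{digits = 17}).
#'
#' @param tab a test-table data.frame
#' @param path output path
#' @export
writeTestTable <- function(tab, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  fmt <- tab
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17)
      }, character(1))
    }
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTestTable
#' @param path TSV path
#' @export
readTestTable <- function(path) {
  readTsv(path)
}
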