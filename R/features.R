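## Binary motif features from promoter and co-accessibility-linked distal
## sequence, and chromosome-level train/validation/test splits.

#' Default expression-model hyperparameters
#'
#' The selected working point: promoter window 1500 bp upstream / 500 bp
#' downstream of the TSS, motif scan p-value cutoff 1e-4, co-accessibility
#' cutoff 0.015, at most 20 distal sites per gene, 1000 bp distal scan
#' windows.
#'
#' @return named list with elements \code{promoterUpstream},
#'   \code{promoterDownstream}, \code{motifPCutoff}, \code{coaccCutoff},
#'   \code{maxDistal}, \code{distalWindow}
#' @export
defaultHyperparameters <- function() {
  list(promoterUpstream = 1500, promoterDownstream = 500,
       motifPCutoff = 1e-4, coaccCutoff = 0.015, maxDistal = 20,
       distalWindow = 1000)
}

#' @noRd
.checkHyperparameters <- function(hp) {
  defaults <- defaultHyperparameters()
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hp <- c(hp, defaults[setdiff(names(defaults), names(hp))])
  .assertScalarNumber(hp$promoterUpstream, "promoterUpstream", 1)
  .assertScalarNumber(hp$promoterDownstream, "promoterDownstream", 1)
  .assertScalarNumber(hp$distalWindow, "distalWindow", 1)
  .assertScalarNumber(hp$motifPCutoff, "motifPCutoff", 1e-300, 1)
  .assertScalarNumber(hp$maxDistal, "maxDistal", 0)
  .assertScalarNumber(hp$coaccCutoff, "coaccCutoff", -1, 1)
  hp
}

#' Strand-oriented promoter windows around gene TSSs
#'
#' Upstream means 5' of the TSS: a plus-strand gene's window spans
#' [TSS - U, TSS + D) and a minus-strand gene's [TSS - D, TSS + U) in
#' 0-based coordinates.
#'
#' @param genes gene table (gene_id, chrom, tss, strand)
#' @param upstream,downstream window extents in bp
#' @return a GRanges named by gene_id
#' @export
promoterWindows <- function(genes, upstream, downstream) {
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1, start0 + 1), end = pmax(1, end0)))
  names(gr) <- genes$gene_id
  gr
}

#' Build binary gene x motif features from promoters and linked distal sites
#'
#' Promoter peaks are the peaks intersecting each protein-coding gene's
#' strand-oriented promoter window. Distal candidates are non-promoter
#' peaks linked (in either direction) to any of the gene's promoter peaks
#' with a co-accessibility score above \code{hp$coaccCutoff}; when more
#' than \code{hp$maxDistal} qualify, the top-scoring ones are kept (ties
#' broken by smaller distance to the TSS, then peak id). A motif feature is
#' 1 iff the motif occurs in any promoter peak (mode
#' \code{"promoter_only"}) or additionally in any peak overlapping a
#' \code{hp$distalWindow}-wide window centered on a selected distal peak
#' (mode \code{"promoter_plus_distal"}).
#'
#' @param genes gene table; non-protein-coding genes are dropped
#' @param peaks named GRanges of peaks
#' @param motifMatrix sparse logical motif x peak matrix, binarized at
#'   \code{hp$motifPCutoff} upstream (e.g. by
#'   \code{\link{readMotifOccurrences}})
#' @param links co-accessibility link table (peak_a, peak_b, score)
#' @param hp hyperparameter list (see \code{\link{defaultHyperparameters}})
#' @param mode \code{"promoter_only"} or \code{"promoter_plus_distal"}
#' @return a \link{MotifFeatures}; genes with no promoter peak get all-zero
#'   rows and are counted in \code{attr(, "nNoPromoter")}
#' @export
buildFeatures <- function(genes, peaks, motifMatrix, links,
                          hp = defaultHyperparameters(),
                          mode = c("promoter_plus_distal", "promoter_only")) {
  mode <- match.arg(mode)
  hp <- .checkHyperparameters(hp)
  genes <- genes[genes$protein_coding, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no protein-coding genes", call. = FALSE)
  peakIds <- names(peaks)
  bad <- setdiff(unique(c(links$peak_a, links$peak_b)), peakIds)
  if (length(bad) > 0L) {
    stop("links reference unknown peaks: ", paste(head(bad, 5),
         collapse = ", "), call. = FALSE)
  }

  prom <- promoterWindows(genes, hp$promoterUpstream, hp$promoterDownstream)
  hits <- GenomicRanges::findOverlaps(prom, peaks)
  promPeaks <- split(peakIds[S4Vectors::subjectHits(hits)],
                     factor(names(prom)[S4Vectors::queryHits(hits)],
                            levels = genes$gene_id))

  strong <- links[links$score > hp$coaccCutoff, , drop = FALSE]
  occ <- motifMatrix * 1
  motifs <- rownames(motifMatrix)
  peakCenter <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2

  featRows <- vector("list", nrow(genes))
  provenance <- vector("list", nrow(genes))
  nNoPromoter <- 0L
  for (i in seq_len(nrow(genes))) {
    pp <- promPeaks[[genes$gene_id[i]]]
    if (length(pp) == 0L) {
      nNoPromoter <- nNoPromoter + 1L
      featRows[[i]] <- numeric(length(motifs))
      provenance[[i]] <- list(promoter = character(0), distal = character(0))
      next
    }
    distal <- character(0)
    if (mode == "promoter_plus_distal" && hp$maxDistal > 0) {
      sel <- strong$peak_a %in% pp | strong$peak_b %in% pp
      cand <- strong[sel, , drop = FALSE]
      other <- ifelse(cand$peak_a %in% pp, cand$peak_b, cand$peak_a)
      keep <- !(other %in% pp)
      cand <- data.frame(peak = other[keep], score = cand$score[keep],
                         stringsAsFactors = FALSE)
      if (nrow(cand) > 0L) {
        ## one candidate per peak at its best score
        cand <- cand[order(cand$peak, -cand$score), , drop = FALSE]
        cand <- cand[!duplicated(cand$peak), , drop = FALSE]
        dist <- abs(peakCenter[match(cand$peak, peakIds)] - genes$tss[i])
        ord <- order(-cand$score, dist, cand$peak)
        distal <- cand$peak[ord][seq_len(min(hp$maxDistal, nrow(cand)))]
      }
    }
    contributing <- pp
    if (length(distal) > 0L) {
      win <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(peaks[distal])),
        IRanges::IRanges(
          start = pmax(1, round(peakCenter[match(distal, peakIds)] -
                                  hp$distalWindow / 2)),
          width = hp$distalWindow))
      inWin <- GenomicRanges::findOverlaps(win, peaks)
      contributing <- union(contributing,
                            peakIds[S4Vectors::subjectHits(inWin)])
    }
    featRows[[i]] <- as.numeric(
      Matrix::rowSums(occ[, contributing, drop = FALSE]) > 0)
    provenance[[i]] <- list(promoter = pp, distal = distal)
  }
  mat <- Matrix::Matrix(do.call(rbind, featRows), sparse = TRUE,
                        dimnames = list(genes$gene_id, motifs))
  names(provenance) <- genes$gene_id
  out <- new("MotifFeatures", matrix = mat, mode = mode,
             hyperparameters = hp, provenance = provenance)
  attr(out, "nNoPromoter") <- nNoPromoter
  out
}

#' Assign chromosomes to train/validation/test partitions
#'
#' Whole chromosomes are assigned (no gene's chromosome straddles
#' partitions): chromosomes are shuffled under the seed, then greedily
#' placed in the partition with the largest remaining gene-count deficit
#' relative to the target fractions.
#'
#' @param genes gene table (gene_id, chrom)
#' @param fractions length-3 target gene fractions (train, validation,
#'   test), summing to 1
#' @param seed integer seed
#' @return list with \code{assignment} (data.frame chrom/partition/genes)
#'   and per-partition chromosome vectors \code{train}, \code{validation},
#'   \code{test}
#' @export
splitByChromosome <- function(genes, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  chroms <- unique(genes$chrom)
  if (length(chroms) < 3) {
    stop("need >= 3 chromosomes for a train/validation/test split",
         call. = FALSE)
  }
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  }
  counts <- table(genes$chrom)[chroms]
  withr::local_seed(childSeed(seed, "chromsplit"))
  ord <- sample(seq_along(chroms))
  chroms <- chroms[ord]
  counts <- as.integer(counts[ord])

  parts <- c("train", "validation", "test")
  total <- sum(counts)
  assigned <- setNames(numeric(3), parts)
  label <- character(length(chroms))
  for (i in order(-counts)) {
    deficit <- fractions * total - assigned
    p <- which.max(deficit)
    label[i] <- parts[p]
    assigned[p] <- assigned[p] + counts[i]
  }
  ## every partition must be non-empty; steal the smallest chromosome of the
  ## largest partition if needed
  for (p in parts) {
    if (!p %in% label) {
      donorPart <- names(which.max(assigned))
      cand <- which(label == donorPart)
      j <- cand[which.min(counts[cand])]
      assigned[donorPart] <- assigned[donorPart] - counts[j]
      assigned[p] <- counts[j]
      label[j] <- p
    }
  }
  assignment <- data.frame(chrom = chroms, partition = label,
                           genes = counts, stringsAsFactors = FALSE)
  list(assignment = assignment,
       train = chroms[label == "train"],
       validation = chroms[label == "validation"],
       test = chroms[label == "test"])
}

#' @noRd
.splitGenes <- function(genes, split, partition) {
  genes$gene_id[genes$chrom %in% split[[partition]]]
}
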