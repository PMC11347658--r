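## Independent brute-force oracles used by unit and acceptance tests.
## These deliberately avoid the package's own code paths.

#' Triple-loop motif x cell count oracle
bruteMotifCellCounts <- function(motifMat, accessMat) {
  motifMat <- as.matrix(motifMat) * 1
  accessMat <- as.matrix(accessMat)
  out <- matrix(0, nrow(motifMat), ncol(accessMat),
                dimnames = list(rownames(motifMat), colnames(accessMat)))
  for (m in seq_len(nrow(motifMat))) {
    for (c in seq_len(ncol(accessMat))) {
      acc <- 0
      for (p in seq_len(ncol(motifMat))) {
        if (motifMat[m, p] > 0 && accessMat[p, c] > 0) acc <- acc + 1
      }
      out[m, c] <- acc
    }
  }
  out
}

#' Step-up BH oracle (textbook formula)
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Independent weighted-KS enrichment score (loop implementation)
bruteGseaES <- function(stats, members, weight = 1) {
  ord <- order(-stats, names(stats))
  genes <- names(stats)[ord]
  z <- abs(stats[ord])^weight
  isHit <- genes %in% members
  K <- sum(isHit); N <- length(genes)
  nr <- sum(z[isHit])
  run <- 0; best <- 0; z <- as.numeric(z)
  for (i in seq_len(N)) {
    if (isHit[i]) {
      run <- run + (if (nr > 0) z[i] / nr else 1 / K)
    } else {
      run <- run - 1 / (N - K)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

#' Exhaustive GSEA permutation p-value oracle (sign-matched tail)
bruteGseaExactP <- function(stats, members, weight = 1) {
  obs <- bruteGseaES(stats, members, weight)
  genes <- names(stats)
  K <- length(intersect(members, genes))
  combos <- combn(genes, K)
  nullES <- apply(combos, 2, function(g) bruteGseaES(stats, g, weight))
  pool <- if (obs >= 0) nullES[nullES >= 0] else nullES[nullES < 0]
  sum(abs(pool) >= abs(obs)) / max(1L, length(pool))
}

#' Per-gene brute-force feature reconstruction (independent rescan over all
#' peaks and links); coordinates handled in 0-based half-open space.
bruteFeatures <- function(genes, peaks, motifMat, links, hp, mode) {
  motifMat <- as.matrix(motifMat) * 1
  peakIds <- names(peaks)
  pStart0 <- GenomicRanges::start(peaks) - 1
  pEnd0 <- GenomicRanges::end(peaks)
  pChrom <- as.character(GenomicRanges::seqnames(peaks))
  pCenter <- (pStart0 + pEnd0) / 2
  genes <- genes[genes$protein_coding, , drop = FALSE]
  out <- matrix(0, nrow(genes), nrow(motifMat),
                dimnames = list(genes$gene_id, rownames(motifMat)))
  overlaps <- function(aS, aE, bS, bE) aS < bE && bS < aE
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      wS <- tss - hp$promoterUpstream; wE <- tss + hp$promoterDownstream
    } else {
      wS <- tss - hp$promoterDownstream; wE <- tss + hp$promoterUpstream
    }
    prom <- character(0)
    for (p in seq_along(peakIds)) {
      if (pChrom[p] == genes$chrom[i] &&
          overlaps(wS, wE, pStart0[p], pEnd0[p])) {
        prom <- c(prom, peakIds[p])
      }
    }
    contributing <- prom
    if (mode == "promoter_plus_distal" && length(prom) > 0 &&
        hp$maxDistal > 0) {
      cand <- data.frame(peak = character(0), score = numeric(0))
      for (j in seq_len(nrow(links))) {
        if (links$score[j] <= hp$coaccCutoff) next
        a <- links$peak_a[j]; b <- links$peak_b[j]
        other <- if (a %in% prom) b else if (b %in% prom) a else NA
        if (is.na(other) || other %in% prom) next
        cand <- rbind(cand, data.frame(peak = other, score = links$score[j]))
      }
      if (nrow(cand) > 0) {
        cand <- cand[order(cand$peak, -cand$score), , drop = FALSE]
        cand <- cand[!duplicated(cand$peak), , drop = FALSE]
        d <- abs(pCenter[match(cand$peak, peakIds)] - tss)
        cand <- cand[order(-cand$score, d, cand$peak), , drop = FALSE]
        distal <- head(cand$peak, hp$maxDistal)
        for (dp in distal) {
          ix <- match(dp, peakIds)
          wS2 <- round(pCenter[ix] - hp$distalWindow / 2)
          wE2 <- wS2 + hp$distalWindow
          for (p in seq_along(peakIds)) {
            if (pChrom[p] == pChrom[ix] &&
                overlaps(wS2, wE2, pStart0[p], pEnd0[p])) {
              contributing <- c(contributing, peakIds[p])
            }
          }
        }
      }
    }
    contributing <- unique(contributing)
    if (length(contributing) > 0) {
      out[i, ] <- as.numeric(
        rowSums(motifMat[, contributing, drop = FALSE]) > 0)
    }
  }
  out
}
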