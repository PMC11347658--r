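## Preranked gene-set enrichment with a permutation null.
##
## The enrichment score is the classic max-deviation weighted
## Kolmogorov-Smirnov running sum over the z-ranked gene list (weight
## |z|^w, default w = 1); the null is random gene-label permutations of set
## membership, the only permutation scheme available for preranked input.

#' @noRd
.gseaES <- function(ord, zAbsW, isHit, wantEdge = FALSE) {
  K <- sum(isHit)
  N <- length(ord)
  nr <- sum(zAbsW[isHit])
  delta <- rep(-1 / (N - K), N)
  if (nr > 0) {
    delta[isHit] <- zAbsW[isHit] / nr
  } else {
    delta[isHit] <- 1 / K  # all-zero statistics: fall back to equal weights
  }
  rs <- cumsum(delta)
  iMax <- which.max(abs(rs))
  es <- rs[iMax]
  if (!wantEdge) return(es)
  hits <- which(isHit)
  edge <- if (es >= 0) hits[hits <= iMax] else hits[hits >= iMax]
  list(es = es, edgeIdx = edge)
}

#' Preranked permutation GSEA
#'
#' Ranks the universe by decreasing z-statistic (ties broken by stable gene
#' id order), computes the weighted KS enrichment score for each gene set,
#' and compares it against a null of random same-size memberships. The
#' two-sided p-value is the sign-matched tail probability with add-one
#' smoothing, so p >= 1/(nPerm + 1); NES divides the observed ES by the
#' mean |null ES| of the same sign. Sets overlapping the universe in fewer
#' than 2 genes are skipped with a warning.
#'
#' @param stats named numeric vector: gene -> z-statistic
#' @param sets named list of gene-id vectors (e.g. \code{\link{readGmt}})
#' @param nPerm permutations per set (>= 100)
#' @param seed integer seed; results are bit-identical under a fixed seed
#'   and independent of set order
#' @param weight exponent w on |z| (0 or 1; default 1)
#' @param exhaustive enumerate all same-size memberships instead of
#'   sampling (exact permutation p; feasible only for tiny universes)
#' @return data.frame: set, size, ES, NES, p, q, leading_edge
#'   (comma-separated), n_perm, plus the seed as an attribute
#' @export
prerankedGsea <- function(stats, sets, nPerm = 1000, seed = 1, weight = 1,
                          exhaustive = FALSE) {
  if (length(stats) < 2) stop("need >= 2 ranked genes", call. = FALSE)
  if (!exhaustive && nPerm < 100) stop("nPerm must be >= 100", call. = FALSE)
  if (!weight %in% c(0, 1)) stop("weight must be 0 or 1", call. = FALSE)
  if (is.null(names(stats))) stop("stats must be named by gene", call. = FALSE)

  ord <- order(-stats, names(stats))
  genes <- names(stats)[ord]
  z <- stats[ord]
  zAbsW <- if (weight == 0) rep(1, length(z)) else abs(z)
  N <- length(genes)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], genes)
    K <- length(members)
    if (K < 2) {
      warning("set '", nm, "' has fewer than 2 genes in the universe; skipped")
      return(NULL)
    }
    isHit <- genes %in% members
    obs <- .gseaES(ord, zAbsW, isHit, wantEdge = TRUE)

    if (exhaustive) {
      combos <- combn(N, K)
      nullES <- apply(combos, 2, function(ix) {
        h <- rep(FALSE, N); h[ix] <- TRUE
        .gseaES(ord, zAbsW, h)
      })
      nPermUsed <- ncol(combos)
      sameSign <- if (obs$es >= 0) nullES >= 0 else nullES < 0
      pool <- nullES[sameSign]
      p <- sum(abs(pool) >= abs(obs$es)) / max(1L, length(pool))
    } else {
      withr::local_seed(childSeed(seed, paste0("gsea/", nm)))
      nullES <- vapply(seq_len(nPerm), function(i) {
        h <- rep(FALSE, N); h[sample.int(N, K)] <- TRUE
        .gseaES(ord, zAbsW, h)
      }, numeric(1))
      nPermUsed <- nPerm
      sameSign <- if (obs$es >= 0) nullES >= 0 else nullES < 0
      pool <- nullES[sameSign]
      p <- (1 + sum(abs(pool) >= abs(obs$es))) / (1 + length(pool))
    }
    denom <- mean(abs(pool))
    nes <- if (isTRUE(denom > 0)) obs$es / denom else NA_real_
    data.frame(set = nm, size = K, ES = obs$es, NES = nes, p = p,
               leading_edge = paste(genes[obs$edgeIdx], collapse = ","),
               n_perm = nPermUsed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), q = numeric(0),
                      leading_edge = character(0), n_perm = integer(0)))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "ES", "NES", "p", "q", "leading_edge",
                 "n_perm")]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}
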