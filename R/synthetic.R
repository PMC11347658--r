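## Synthetic multi-donor snRNA + snATAC study with planted effects.
##
## The generator mirrors the statistical structure the analysis models
## assume: negative-binomial gene counts with a log-normal per-(gene, donor)
## random intercept and a log-depth offset, quasi-binary peak accessibility
## with multiplicative covariate effects, logistic-normal cell-type
## composition with donor-level logit intercepts, and pseudo-bulk expected
## log2 expression that is exactly linear in binary motif features split
## between promoter and linked distal sites.

HEART_SITES <- c("LV", "RV", "septum", "apex")

## sampling concentrates on the left ventricle and apex, as cardiac
## collections typically do; RV/septum specimens are occasional
HEART_SITE_WEIGHTS <- c(LV = 0.45, RV = 0.1, septum = 0.08, apex = 0.37)

HEART_CELL_TYPES <- c("cardiomyocyte", "fibroblast", "macrophage",
                      "vascular_endothelium", "pericyte", "smooth_muscle",
                      "neuron", "adipocyte")

HEART_BASE_PROPS <- c(0.32, 0.22, 0.13, 0.11, 0.08, 0.06, 0.05, 0.03)

#' Generate a multi-donor cohort
#'
#' Sexes are assigned in a balanced alternation, ages drawn uniformly on
#' \code{ageRange}, donors spread evenly over \code{studyLabels}, and each
#' donor is assigned anatomical sites from \{LV, RV, septum, apex\}.
#'
#' @param nDonors number of donors (>= 2; mixed models are undefined below
#'   that)
#' @param ageRange numeric length-2 vector of minimum and maximum age in
#'   years
#' @param studyLabels character vector of study/data-source labels
#' @param sitesPerDonor sites sampled per donor; either a fixed count (1-4)
#'   or NULL to draw 1-3 sites per donor
#' @param seed integer seed; the same call with the same seed is
#'   bit-identical
#' @return data.frame with columns \code{donor_id}, \code{age}, \code{sex},
#'   \code{study}, \code{sites} (comma-separated)
#' @export
generateCohort <- function(nDonors = 8, ageRange = c(25, 70),
                           studyLabels = "this_study", sitesPerDonor = 2,
                           seed = 1) {
  if (nDonors < 2) {
    stop("cohort too small: mixed models need >= 2 donors", call. = FALSE)
  }
  if (length(ageRange) != 2L || ageRange[1] <= 0 || ageRange[2] < ageRange[1]) {
    stop("invalid ageRange", call. = FALSE)
  }
  withr::local_seed(childSeed(seed, "cohort"))
  sex <- rep(c("F", "M"), length.out = nDonors)
  study <- sort(rep(studyLabels, length.out = nDonors))
  sites <- vapply(seq_len(nDonors), function(i) {
    k <- if (is.null(sitesPerDonor)) sample(1:3, 1) else sitesPerDonor
    paste(sample(HEART_SITES, k, prob = HEART_SITE_WEIGHTS), collapse = ",")
  }, character(1))
  data.frame(
    donor_id = sprintf("donor_%02d", seq_len(nDonors)),
    age = round(runif(nDonors, ageRange[1], ageRange[2]), 1),
    sex = sex,
    study = study,
    sites = sites,
    stringsAsFactors = FALSE
  )
}

#' Expand a cohort into its (donor, site) sample table
#'
#' @param cohort output of \code{\link{generateCohort}}
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{donor_id}, \code{site}, plus donor covariates
#' @export
donorSamples <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sites <- strsplit(cohort$sites[i], ",", fixed = TRUE)[[1]]
    data.frame(
      sample_id = paste0(cohort$donor_id[i], "_", sites),
      donor_id = cohort$donor_id[i],
      site = sites,
      age = cohort$age[i],
      sex = cohort$sex[i],
      study = cohort$study[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Generate a synthetic genome: genes, peaks, motif occurrences and links
#'
#' Each gene receives one peak overlapping its promoter and several distal
#' peaks 6-45 kb away (spaced so that distal scan windows never capture a
#' neighboring peak). A random subset of distal peaks is designated truly
#' regulatory and linked to the gene's promoter peak with a high
#' co-accessibility score; additional noise links carry scores below any
#' useful cutoff. Motif occurrences are independent Bernoulli draws at
#' \code{motifDensity}, except designated grammar motifs, which are planted
#' into the promoter peaks (promoter-acting) or truly linked distal peaks
#' (distal-acting) of their target genes.
#'
#' @param nChrom,genesPerChrom,peaksPerGene genome dimensions;
#'   \code{peaksPerGene >= 2} so distal peaks exist
#' @param nMotifs motif universe size
#' @param motifDensity background occurrence probability in (0, 1)
#' @param nGrammarMotifs number of motifs carrying planted expression
#'   grammar, split evenly between promoter-acting and distal-acting
#' @param grammarTargetFrac fraction of genes targeted by each grammar motif
#' @param grammarEnrichProb occurrence probability in a target peak
#' @param seed integer seed
#' @return list with \code{genes}, \code{peaks} (GRanges), \code{motifMatrix}
#'   (sparse logical motif x peak), \code{links}, \code{genePeaks} (per-gene
#'   promoter / distal / true-distal peak ids) and \code{grammar}
#'   (promoter-/distal-acting motif names)
#' @export
generateGenome <- function(nChrom = 5, genesPerChrom = 40, peaksPerGene = 5,
                           nMotifs = 50, motifDensity = 0.05,
                           nGrammarMotifs = 6, grammarTargetFrac = 0.4,
                           grammarEnrichProb = 0.9, seed = 1) {
  stopifnot(nChrom >= 1, genesPerChrom >= 1, nMotifs >= 1)
  if (peaksPerGene < 2) {
    stop("peaksPerGene must be >= 2: cannot place distal peaks", call. = FALSE)
  }
  if (motifDensity <= 0 || motifDensity >= 1) {
    stop("motifDensity must be in (0, 1)", call. = FALSE)
  }
  withr::local_seed(childSeed(seed, "genome"))

  nGenes <- nChrom * genesPerChrom
  chrom <- rep(sprintf("chr%d", seq_len(nChrom)), each = genesPerChrom)
  idx <- rep(seq_len(genesPerChrom), times = nChrom)
  tss <- 50000 + (idx - 1) * 100000
  strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  coding <- runif(nGenes) > 0.05
  genes <- data.frame(
    gene_id = sprintf("gene_%03d", seq_len(nGenes)),
    chrom = chrom, tss = tss, strand = strand,
    protein_coding = coding, stringsAsFactors = FALSE
  )

  ## promoter peak straddles the TSS; distal peaks on a 2 kb grid with small
  ## jitter so no two peaks fall within one distal scan window (<= 1 kb)
  peakRows <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    pStart <- tss[g] - 250
    nDistal <- peaksPerGene - 1L
    offGrid <- sample(seq(6000, 44000, by = 2000), nDistal)
    offs <- offGrid + sample(-300:300, nDistal, replace = TRUE)
    offs <- offs * sample(c(-1, 1), nDistal, replace = TRUE)
    starts <- c(pStart, tss[g] + offs - 250)
    peakRows[[g]] <- data.frame(
      chrom = chrom[g], start = starts, end = starts + 500,
      gene = genes$gene_id[g],
      role = c("promoter", rep("distal", nDistal)),
      stringsAsFactors = FALSE
    )
  }
  pk <- do.call(rbind, peakRows)
  ord <- order(pk$chrom, pk$start)
  pk <- pk[ord, , drop = FALSE]
  pk$peak_id <- sprintf("peak_%05d", seq_len(nrow(pk)))
  peaks <- GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(start = pk$start + 1, end = pk$end))
  names(peaks) <- pk$peak_id

  genePeaks <- lapply(genes$gene_id, function(g) {
    rows <- pk[pk$gene == g, , drop = FALSE]
    distal <- rows$peak_id[rows$role == "distal"]
    nTrue <- max(1L, rbinom(1, length(distal), 0.6))
    list(promoter = rows$peak_id[rows$role == "promoter"],
         distal = distal,
         true_distal = sort(sample(distal, nTrue)))
  })
  names(genePeaks) <- genes$gene_id

  ## true regulatory links (high score) plus low-score noise links
  trueLinks <- do.call(rbind, lapply(genes$gene_id, function(g) {
    gp <- genePeaks[[g]]
    data.frame(peak_a = gp$promoter, peak_b = gp$true_distal,
               score = round(runif(length(gp$true_distal), 0.1, 0.6), 4),
               stringsAsFactors = FALSE)
  }))
  nNoise <- max(1L, round(nGenes / 2))
  noiseLinks <- data.frame(
    peak_a = sample(pk$peak_id, nNoise, replace = TRUE),
    peak_b = sample(pk$peak_id, nNoise, replace = TRUE),
    score = round(runif(nNoise, 0, 0.012), 5),
    stringsAsFactors = FALSE
  )
  noiseLinks <- noiseLinks[noiseLinks$peak_a != noiseLinks$peak_b, ,
                           drop = FALSE]
  links <- canonicalLinks(rbind(trueLinks, noiseLinks))

  motifIds <- sprintf("motif_%03d", seq_len(nMotifs))
  occ <- matrix(runif(nMotifs * nrow(pk)) < motifDensity,
                nrow = nMotifs,
                dimnames = list(motifIds, pk$peak_id))

  grammar <- list(promoter = character(0), distal = character(0),
                  targets = list())
  if (nGrammarMotifs > 0) {
    if (nGrammarMotifs > nMotifs) stop("more grammar motifs than motifs")
    gm <- motifIds[seq_len(nGrammarMotifs)]
    half <- ceiling(nGrammarMotifs / 2)
    grammar$promoter <- gm[seq_len(half)]
    grammar$distal <- gm[setdiff(seq_len(nGrammarMotifs), seq_len(half))]
    for (m in gm) {
      targets <- sample(genes$gene_id,
                        max(1L, round(grammarTargetFrac * nGenes)))
      grammar$targets[[m]] <- sort(targets)
      for (g in targets) {
        gp <- genePeaks[[g]]
        where <- if (m %in% grammar$promoter) gp$promoter else gp$true_distal
        hit <- runif(length(where)) < grammarEnrichProb
        occ[m, where[hit]] <- TRUE
      }
    }
  }
  motifMatrix <- as(Matrix::Matrix(occ, sparse = TRUE), "lMatrix")
  attr(motifMatrix, "scan_p_cutoff") <- 1e-7

  list(genes = genes, peaks = peaks, motifMatrix = motifMatrix,
       links = links, genePeaks = genePeaks, grammar = grammar,
       motifDensity = motifDensity)
}

#' Construct the planted-effects (ground truth) object for a synthetic study
#'
#' Effect vectors default to all-zero ("null study") unless planting counts
#' are requested. Planted motif effects alternate in sign so that motif
#' co-occurrence does not systematically bias single-motif estimates; planted
#' gene effects are shared across cell types. Grammar coefficients (log2
#' expression per motif presence) are drawn once per (cell type, motif) with
#' magnitudes in [0.6, 1.5].
#'
#' @param genome output of \code{\link{generateGenome}}
#' @param nMotifSex,nMotifAge number of motifs with planted sex/age
#'   accessibility effects (chosen among non-grammar motifs)
#' @param motifSexEffect,motifAgeEffect planted magnitudes (log scale per
#'   unit; age is per year)
#' @param nGeneSex,nGeneAge number of genes with planted expression effects
#' @param geneSexEffect,geneAgeEffect planted magnitudes
#' @param propSitePlant optional list(cellType=, site=, beta=) planting a
#'   logit-scale site effect on one cell type's proportion
#' @param propSexBeta,propAgeBeta named per-cell-type logit-scale
#'   composition effects (defaults plant a cardiomyocyte sex shift and a
#'   neuron age decline, the two signals the heart analyses look for)
#' @param motifTypePlant named character vector mapping motif id -> cell
#'   type whose preferred peaks that motif concentrates in (drives
#'   cell-type-dummy enrichment)
#' @param donorReSd sd of per-(feature, donor) log-scale random intercepts
#' @param propReSd sd of per-(cell type, donor) logit intercepts
#' @param dispersion negative-binomial size parameter for RNA counts
#' @param qcFailFrac fraction of cells planted to fail QC
#' @param geneBaselineSd,typeNoiseSd sd of per-gene and per-(gene, cell
#'   type) baseline log2-expression noise around the motif-grammar signal;
#'   set both to 0 for a noiseless grammar
#' @param grammarSeed seed for drawing grammar coefficients
#' @param studyShiftSd sd of the per-(study, gene) mean shift applied when
#'   the cohort spans several studies
#' @return a list of planted effects consumed by \code{\link{generateCounts}}
#' @export
plantedEffects <- function(genome,
                         nMotifSex = 0, nMotifAge = 0,
                         motifSexEffect = 0.5, motifAgeEffect = 0.015,
                         nGeneSex = 0, nGeneAge = 0,
                         geneSexEffect = 0.5, geneAgeEffect = 0.015,
                         propSexBeta = NULL, propAgeBeta = NULL,
                         propSitePlant = NULL,
                         motifTypePlant = NULL,
                         donorReSd = 0.5, propReSd = 0.3,
                         sampleNoiseSd = 0.3,
                         dispersion = 2, atacDispersion = 3,
                         qcFailFrac = 0.05,
                         geneBaselineSd = 1.0, typeNoiseSd = 0.3,
                         grammarSeed = 1, studyShiftSd = 0.3) {
  motifs <- rownames(genome$motifMatrix)
  geneIds <- genome$genes$gene_id
  types <- HEART_CELL_TYPES
  nT <- length(types)

  withr::local_seed(childSeed(grammarSeed, "truth"))

  zeroM <- setNames(numeric(length(motifs)), motifs)
  motifSexBeta <- motifAgeBeta <- zeroM
  free <- setdiff(motifs, c(genome$grammar$promoter, genome$grammar$distal))
  if (nMotifSex > 0) {
    pick <- sample(free, nMotifSex)
    motifSexBeta[pick] <- motifSexEffect * rep(c(1, -1), length.out = nMotifSex)
    free <- setdiff(free, pick)
  }
  if (nMotifAge > 0) {
    pick <- sample(free, nMotifAge)
    motifAgeBeta[pick] <- motifAgeEffect * rep(c(1, -1), length.out = nMotifAge)
  }

  geneSexBeta <- matrix(0, length(geneIds), nT,
                        dimnames = list(geneIds, types))
  geneAgeBeta <- geneSexBeta
  if (nGeneSex > 0) {
    pick <- sample(geneIds, nGeneSex)
    geneSexBeta[pick, ] <- geneSexEffect * rep(c(1, -1), length.out = nGeneSex)
  }
  if (nGeneAge > 0) {
    pick <- sample(setdiff(geneIds, rownames(geneSexBeta)[
      rowSums(geneSexBeta != 0) > 0]), nGeneAge)
    geneAgeBeta[pick, ] <- geneAgeEffect * rep(c(1, -1), length.out = nGeneAge)
  }

  zeroT <- setNames(numeric(nT), types)
  ps <- zeroT
  pa <- zeroT
  if (!is.null(propSexBeta)) ps[names(propSexBeta)] <- propSexBeta
  if (!is.null(propAgeBeta)) pa[names(propAgeBeta)] <- propAgeBeta

  ## grammar coefficients: every cell type carries signal on every grammar
  ## motif so promoter/distal comparisons are informative in all types
  gm <- c(genome$grammar$promoter, genome$grammar$distal)
  grammarPromoterBeta <- matrix(0, nT, length(motifs),
                                dimnames = list(types, motifs))
  grammarDistalBeta <- grammarPromoterBeta
  for (m in genome$grammar$promoter) {
    grammarPromoterBeta[, m] <- runif(nT, 0.6, 1.5) *
      sample(c(-1, 1), nT, replace = TRUE)
  }
  for (m in genome$grammar$distal) {
    grammarDistalBeta[, m] <- runif(nT, 0.6, 1.5) *
      sample(c(-1, 1), nT, replace = TRUE)
  }

  list(
    motifSexBeta = motifSexBeta, motifAgeBeta = motifAgeBeta,
    geneSexBeta = geneSexBeta, geneAgeBeta = geneAgeBeta,
    propSexBeta = ps, propAgeBeta = pa,
    propSitePlant = propSitePlant,
    motifTypePlant = motifTypePlant,
    grammarPromoterBeta = grammarPromoterBeta,
    grammarDistalBeta = grammarDistalBeta,
    donorReSd = donorReSd, propReSd = propReSd,
    sampleNoiseSd = sampleNoiseSd,
    dispersion = dispersion, atacDispersion = atacDispersion,
    qcFailFrac = qcFailFrac,
    geneBaselineSd = geneBaselineSd, typeNoiseSd = typeNoiseSd,
    studyShiftSd = studyShiftSd
  )
}

#' Gene x motif binary features implied by the generator's own provenance
#'
#' Promoter features mark motif occurrences in a gene's promoter peak;
#' distal features mark occurrences in its truly linked distal peaks. These
#' are the design matrices the grammar acts through, computed directly from
#' generator bookkeeping (independently of \code{\link{buildFeatures}}).
#'
#' @param genome output of \code{\link{generateGenome}}
#' @return list of two genes x motifs logical matrices, \code{promoter} and
#'   \code{distal}
#' @export
truthFeatures <- function(genome) {
  occ <- as.matrix(genome$motifMatrix)
  geneIds <- genome$genes$gene_id
  motifs <- rownames(occ)
  prom <- matrix(FALSE, length(geneIds), length(motifs),
                 dimnames = list(geneIds, motifs))
  dist <- prom
  for (g in geneIds) {
    gp <- genome$genePeaks[[g]]
    prom[g, ] <- apply(occ[, gp$promoter, drop = FALSE], 1, any)
    dist[g, ] <- apply(occ[, gp$true_distal, drop = FALSE], 1, any)
  }
  list(promoter = prom, distal = dist)
}

#' Generate counts, cells and QC fields for a synthetic study
#'
#' Cell types are drawn per (donor, site) sample from a logistic-normal
#' composition with planted logit effects and donor intercepts. RNA counts
#' are negative binomial with log-mean = baseline + covariate effects +
#' per-(gene, donor) intercept + log-depth offset. ATAC counts are
#' quasi-binary peak accessibilities (presence/absence, as sci-ATAC counts
#' effectively are) with multiplicative covariate effects through planted
#' motif betas, a global per-donor accessibility intercept, and per-(peak,
#' donor) noise. QC fields are populated with a planted fraction of
#' QC-failing cells; 2-D embedding coordinates place cells of each type in a
#' shared cluster for both modalities.
#'
#' @param cohort output of \code{\link{generateCohort}}
#' @param genome output of \code{\link{generateGenome}}
#' @param truth output of \code{\link{plantedEffects}}
#' @param cellsPerSample nuclei per (donor, site) sample and modality
#' @param seed integer seed
#' @return a \link{HeartStudy}
#' @export
generateCounts <- function(cohort, genome, truth, cellsPerSample = 300,
                           seed = 1) {
  types <- HEART_CELL_TYPES
  nT <- length(types)
  geneIds <- genome$genes$gene_id
  peakIds <- names(genome$peaks)
  nG <- length(geneIds)
  nP <- length(peakIds)
  if (!identical(rownames(truth$geneSexBeta), geneIds)) {
    stop("truth/genome dimension mismatch: gene effect rows do not match genes",
         call. = FALSE)
  }
  if (!identical(names(truth$motifSexBeta), rownames(genome$motifMatrix))) {
    stop("truth/genome dimension mismatch: motif effects do not match motifs",
         call. = FALSE)
  }
  samples <- donorSamples(cohort)
  nS <- nrow(samples)
  donors <- cohort$donor_id
  studies <- sort(unique(cohort$study))

  ## --- expected log2 expression per (gene, cell type): motif grammar ----
  withr::local_seed(childSeed(seed, "expression"))
  feats <- truthFeatures(genome)
  base <- rnorm(nG, 0, truth$geneBaselineSd)
  typeNoise <- matrix(rnorm(nG * nT, 0, truth$typeNoiseSd), nG, nT)
  ## one coefficient per grammar motif, acting through the motif's overall
  ## presence near the gene (promoter or linked distal site) so that the
  ## binary-union design the expression model fits can represent the truth
  featUnion <- feats$promoter | feats$distal
  expectedLog2Tpm <- 4 + base + typeNoise +
    featUnion %*% t(truth$grammarPromoterBeta + truth$grammarDistalBeta)
  dimnames(expectedLog2Tpm) <- list(geneIds, types)
  relAbundance <- 2^expectedLog2Tpm
  relAbundance <- sweep(relAbundance, 2, colSums(relAbundance), "/")

  ## per-(study, gene) mean shift (meta-analysis batch structure)
  studyShift <- matrix(0, nG, length(studies),
                       dimnames = list(geneIds, studies))
  if (length(studies) > 1) {
    studyShift[, -1] <- rnorm(nG * (length(studies) - 1), 0,
                              truth$studyShiftSd)
  }

  ## --- composition ------------------------------------------------------
  withr::local_seed(childSeed(seed, "composition"))
  propRe <- matrix(rnorm(length(donors) * nT, 0, truth$propReSd),
                   length(donors), nT, dimnames = list(donors, types))
  eta <- matrix(log(HEART_BASE_PROPS), nS, nT, byrow = TRUE)
  male <- as.numeric(samples$sex == "M")
  eta <- eta +
    outer(samples$age, truth$propAgeBeta) +
    outer(male, truth$propSexBeta) +
    propRe[samples$donor_id, , drop = FALSE] +
    matrix(rnorm(nS * nT, 0, truth$sampleNoiseSd), nS, nT)
  if (!is.null(truth$propSitePlant)) {
    sp <- truth$propSitePlant
    eta[samples$site == sp$site, match(sp$cellType, types)] <-
      eta[samples$site == sp$site, match(sp$cellType, types)] + sp$beta
  }
  comp <- exp(eta) / rowSums(exp(eta))
  typeCounts <- t(vapply(seq_len(nS), function(s) {
    drop(rmultinom(1, cellsPerSample, comp[s, ]))
  }, integer(nT)))
  colnames(typeCounts) <- types

  makeCells <- function(prefix) {
    rows <- lapply(seq_len(nS), function(s) {
      ct <- rep(types, typeCounts[s, ])
      if (length(ct) == 0L) return(NULL)
      data.frame(
        donor_id = samples$donor_id[s], site = samples$site[s],
        age = samples$age[s], sex = samples$sex[s],
        study = samples$study[s], cell_type = ct,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$cell_id <- sprintf("%s_%05d", prefix, seq_len(nrow(out)))
    out
  }
  rnaCells <- makeCells("rna")
  atacCells <- makeCells("atac")
  nRna <- nrow(rnaCells)
  nAtac <- nrow(atacCells)

  ## --- QC fields --------------------------------------------------------
  withr::local_seed(childSeed(seed, "qc"))
  planFail <- function(n, modes) {
    fail <- runif(n) < truth$qcFailFrac
    reason <- rep(NA_character_, n)
    reason[fail] <- sample(modes, sum(fail), replace = TRUE)
    reason
  }
  rnaFail <- planFail(nRna, c("low_umi", "high_mito", "high_doublet"))
  atacFail <- planFail(nAtac, c("low_frit", "low_frip", "high_doublet"))

  rnaCells$mito_frac <- round(runif(nRna, 0, 0.08), 4)
  rnaCells$doublet_score <- round(runif(nRna, 0, 0.15), 4)
  rnaCells$mito_frac[rnaFail %in% "high_mito"] <-
    round(runif(sum(rnaFail %in% "high_mito"), 0.12, 0.35), 4)
  rnaCells$doublet_score[rnaFail %in% "high_doublet"] <-
    round(runif(sum(rnaFail %in% "high_doublet"), 0.25, 0.8), 4)
  rnaCells$frit <- NA_real_
  rnaCells$frip <- NA_real_

  atacCells$frit <- round(runif(nAtac, 0.09, 0.3), 4)
  atacCells$frip <- round(runif(nAtac, 0.25, 0.6), 4)
  atacCells$doublet_score <- round(runif(nAtac, 0, 0.4), 4)
  atacCells$frit[atacFail %in% "low_frit"] <-
    round(runif(sum(atacFail %in% "low_frit"), 0.01, 0.07), 4)
  atacCells$frip[atacFail %in% "low_frip"] <-
    round(runif(sum(atacFail %in% "low_frip"), 0.05, 0.18), 4)
  atacCells$doublet_score[atacFail %in% "high_doublet"] <-
    round(runif(sum(atacFail %in% "high_doublet"), 0.55, 0.95), 4)
  atacCells$mito_frac <- NA_real_

  ## --- RNA counts -------------------------------------------------------
  withr::local_seed(childSeed(seed, "rna"))
  rnaDepth <- pmax(400, rlnorm(nRna, log(1500), 0.35))
  rnaDepth[rnaFail %in% "low_umi"] <-
    runif(sum(rnaFail %in% "low_umi"), 10, 50)
  donorRe <- matrix(rnorm(nG * length(donors), 0, truth$donorReSd),
                    nG, length(donors), dimnames = list(geneIds, donors))
  tIdx <- match(rnaCells$cell_type, types)
  dIdx <- match(rnaCells$donor_id, donors)
  sIdx <- match(rnaCells$study, studies)
  maleC <- as.numeric(rnaCells$sex == "M")
  logMu <- log(relAbundance[, tIdx, drop = FALSE]) +
    truth$geneAgeBeta[, tIdx, drop = FALSE] *
      rep(rnaCells$age, each = nG) +
    truth$geneSexBeta[, tIdx, drop = FALSE] * rep(maleC, each = nG) +
    donorRe[, dIdx, drop = FALSE] +
    studyShift[, sIdx, drop = FALSE] +
    rep(log(rnaDepth), each = nG)
  rna <- matrix(rnbinom(nG * nRna, mu = exp(logMu),
                        size = truth$dispersion),
                nG, nRna, dimnames = list(geneIds, rnaCells$cell_id))
  rnaCells$total_umi <- colSums(rna)
  rna <- Matrix::Matrix(rna, sparse = TRUE)

  ## --- ATAC accessibility ----------------------------------------------
  withr::local_seed(childSeed(seed, "atac"))
  occ <- as.matrix(genome$motifMatrix)
  peakSex <- drop(crossprod(occ, truth$motifSexBeta))
  peakAge <- drop(crossprod(occ, truth$motifAgeBeta))
  ## sparse accessibility regime: probabilities stay well below 1 so the
  ## log-linear effect model holds after binarization
  baseAcc <- pmin(0.25, 0.06 * rlnorm(nP, 0, 0.4))

  ## peak -> preferred cell type (cell-type-specific accessibility); motifs
  ## planted for a type concentrate their peaks' preference on that type
  prefType <- rep(NA_character_, nP)
  prefIdx <- runif(nP) < 0.4
  prefType[prefIdx] <- sample(types, sum(prefIdx), replace = TRUE,
                              prob = HEART_BASE_PROPS)
  if (!is.null(truth$motifTypePlant)) {
    for (m in names(truth$motifTypePlant)) {
      hits <- which(occ[m, ] > 0)
      take <- hits[runif(length(hits)) < 0.8]
      prefType[take] <- truth$motifTypePlant[[m]]
    }
  }
  typeBoost <- matrix(0, nP, nT, dimnames = list(peakIds, types))
  for (t in seq_len(nT)) typeBoost[which(prefType == types[t]), t] <- 0.7

  atacUmi <- round(pmax(2000, rlnorm(nAtac, log(8000), 0.35)))
  depthFac <- atacUmi / 8000
  ## per-cell openness factor: gamma with mean 1 so motif-level counts are
  ## genuinely negative-binomially overdispersed (size = atacDispersion)
  openness <- rgamma(nAtac, shape = truth$atacDispersion,
                     rate = truth$atacDispersion)
  donorAcc <- setNames(rnorm(length(donors), 0, 0.3), donors)
  peakDonorRe <- matrix(rnorm(nP * length(donors), 0, 0.3),
                        nP, length(donors), dimnames = list(peakIds, donors))
  tIdxA <- match(atacCells$cell_type, types)
  dIdxA <- match(atacCells$donor_id, donors)
  maleA <- as.numeric(atacCells$sex == "M")
  ageA <- atacCells$age
  logP <- log(baseAcc) +
    outer(peakSex, maleA) + outer(peakAge, ageA - 45) +
    typeBoost[, tIdxA, drop = FALSE] +
    peakDonorRe[, dIdxA, drop = FALSE] +
    rep(log(depthFac) + log(openness) + donorAcc[atacCells$donor_id], each = nP)
  pAcc <- pmin(0.9, exp(logP))
  atac <- matrix(as.numeric(runif(nP * nAtac) < pAcc),
                 nP, nAtac, dimnames = list(peakIds, atacCells$cell_id))
  atacCells$total_umi <- atacUmi
  atac <- Matrix::Matrix(atac, sparse = TRUE)

  ## --- embedding --------------------------------------------------------
  withr::local_seed(childSeed(seed, "embedding"))
  angle <- 2 * pi * (seq_len(nT) - 1) / nT
  centers <- cbind(8 * cos(angle), 8 * sin(angle))
  embed <- function(cells, idx) {
    cbind(centers[idx, 1] + rnorm(nrow(cells), 0, 0.7),
          centers[idx, 2] + rnorm(nrow(cells), 0, 0.7))
  }
  rnaEmb <- embed(rnaCells, tIdx)
  atacEmb <- embed(atacCells, tIdxA)
  rnaCells$emb1 <- round(rnaEmb[, 1], 4)
  rnaCells$emb2 <- round(rnaEmb[, 2], 4)
  atacCells$emb1 <- round(atacEmb[, 1], 4)
  atacCells$emb2 <- round(atacEmb[, 2], 4)

  rnaCells$modality <- "RNA"
  atacCells$modality <- "ATAC"
  cols <- c("cell_id", "donor_id", "site", "age", "sex", "study", "modality",
            "cell_type", "total_umi", "mito_frac", "frit", "frip",
            "doublet_score", "emb1", "emb2")
  cells <- rbind(rnaCells[, cols], atacCells[, cols])
  rownames(cells) <- NULL

  truth$qcFail <- data.frame(
    cell_id = c(rnaCells$cell_id, atacCells$cell_id),
    reason = c(rnaFail, atacFail),
    stringsAsFactors = FALSE
  )
  truth$expectedLog2Tpm <- expectedLog2Tpm
  truth$featuresPromoter <- feats$promoter
  truth$featuresDistal <- feats$distal
  truth$studyShift <- studyShift

  new("HeartStudy",
      donors = cohort, cells = cells, genes = genome$genes,
      peaks = genome$peaks,
      motifMatrix = genome$motifMatrix, links = genome$links,
      rna = rna, atac = atac, truth = truth,
      metadata = list(seed = seed, cellsPerSample = cellsPerSample,
                      cellTypes = types, scan_p_cutoff = 1e-7,
                      grammar = genome$grammar,
                      genePeaks = genome$genePeaks))
}

#' Simulate a complete default-scale synthetic study
#'
#' Convenience wrapper chaining \code{\link{generateCohort}},
#' \code{\link{generateGenome}}, \code{\link{plantedTruth}} and
#' \code{\link{generateCounts}}. The default scale (8 donors, 2 sites each,
#' 300 cells per sample and modality, 5 chromosomes x 40 genes, 5 peaks per
#' gene, 50 motifs) is sized so full analysis suites run in minutes.
#'
#' @param nDonors,ageRange,studyLabels,sitesPerDonor cohort parameters
#' @param cellsPerSample nuclei per sample per modality
#' @param nChrom,genesPerChrom,peaksPerGene,nMotifs,motifDensity genome
#'   parameters
#' @param truthArgs list of arguments forwarded to \code{\link{plantedEffects}}
#' @param seed master integer seed streamed to all sub-generators
#' @return a \link{HeartStudy}
#' @export
simulateStudy <- function(nDonors = 8, ageRange = c(25, 70),
                          studyLabels = "this_study", sitesPerDonor = 2,
                          cellsPerSample = 300,
                          nChrom = 5, genesPerChrom = 40, peaksPerGene = 5,
                          nMotifs = 50, motifDensity = 0.05,
                          truthArgs = list(), seed = 1) {
  cohort <- generateCohort(nDonors, ageRange, studyLabels, sitesPerDonor,
                           seed = childSeed(seed, "cohort-stage"))
  genome <- generateGenome(nChrom, genesPerChrom, peaksPerGene, nMotifs,
                           motifDensity, seed = childSeed(seed, "genome-stage"))
  truth <- do.call(plantedEffects, c(list(genome = genome), truthArgs,
                                   list(grammarSeed = childSeed(seed, "truth-stage"))))
  generateCounts(cohort, genome, truth, cellsPerSample,
                 seed = childSeed(seed, "counts-stage"))
}

#' Write a synthetic study to a directory of standard-format files
#'
#' Emits peaks.bed, genes.tsv, motif_occurrences.tsv, links.tsv,
#' rna.mtx/atac.mtx with features/barcodes sidecars, cells.tsv and
#' truth.json. Occurrences present in the binary motif matrix are written
#' with scan p-values below 1e-7; a sprinkle of weak occurrences (p in
#' 1e-6..1e-4) is added so that looser binarization cutoffs load genuinely
#' different matrices.
#'
#' @param study a \link{HeartStudy}
#' @param dir output directory (created)
#' @param weakDensity density of weak extra occurrences
#' @return \code{dir}, invisibly
#' @export
writeStudy <- function(study, dir, weakDensity = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBed(study@peaks, file.path(dir, "peaks.bed"))
  writeTsv(study@genes, file.path(dir, "genes.tsv"))
  writeTsv(study@links, file.path(dir, "links.tsv"))
  writeTsv(study@cells, file.path(dir, "cells.tsv"))
  writeTsv(study@donors, file.path(dir, "donors.tsv"))
  writeMtx(study@rna, file.path(dir, "rna.mtx"),
           file.path(dir, "rna_features.tsv"),
           file.path(dir, "rna_barcodes.tsv"))
  writeMtx(study@atac, file.path(dir, "atac.mtx"),
           file.path(dir, "atac_features.tsv"),
           file.path(dir, "atac_barcodes.tsv"))

  occ <- Matrix::which(study@motifMatrix, arr.ind = TRUE)
  motifs <- rownames(study@motifMatrix)
  peakIds <- colnames(study@motifMatrix)
  withr::local_seed(childSeed(study@metadata$seed %||% 0, "occurrence-pvals"))
  strong <- data.frame(
    motif = motifs[occ[, 1]], peak = peakIds[occ[, 2]],
    score = round(runif(nrow(occ), 8, 20), 3),
    p_value = signif(10^runif(nrow(occ), -12, -7.05), 4),
    stringsAsFactors = FALSE
  )
  nWeak <- round(weakDensity * length(motifs) * length(peakIds))
  weak <- data.frame(
    motif = sample(motifs, nWeak, replace = TRUE),
    peak = sample(peakIds, nWeak, replace = TRUE),
    score = round(runif(nWeak, 3, 8), 3),
    p_value = signif(10^runif(nWeak, -6, -4), 4),
    stringsAsFactors = FALSE
  )
  occAll <- rbind(strong, weak)
  occAll <- occAll[order(occAll$motif, occAll$peak, occAll$p_value), ]
  occAll <- occAll[!duplicated(occAll[, c("motif", "peak")]), ]
  writeTsv(occAll, file.path(dir, "motif_occurrences.tsv"))

  truth <- study@truth
  truthJson <- list(
    motifSexBeta = as.list(truth$motifSexBeta),
    motifAgeBeta = as.list(truth$motifAgeBeta),
    propSexBeta = as.list(truth$propSexBeta),
    propAgeBeta = as.list(truth$propAgeBeta),
    donorReSd = truth$donorReSd, propReSd = truth$propReSd,
    dispersion = truth$dispersion, qcFailFrac = truth$qcFailFrac,
    seed = study@metadata$seed
  )
  jsonlite::write_json(truthJson, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory written by \code{\link{writeStudy}}
#'
#' @param dir study directory
#' @param scanPCutoff binarization cutoff for the motif occurrence file
#' @return a \link{HeartStudy} (without planted truth)
#' @export
readStudy <- function(dir, scanPCutoff = 1e-7) {
  peaks <- readBed(file.path(dir, "peaks.bed"))
  genes <- readGenes(file.path(dir, "genes.tsv"))
  links <- readLinks(file.path(dir, "links.tsv"))
  cells <- readCells(file.path(dir, "cells.tsv"))
  donors <- readTsv(file.path(dir, "donors.tsv"))
  rna <- readMtx(file.path(dir, "rna.mtx"),
                 file.path(dir, "rna_features.tsv"),
                 file.path(dir, "rna_barcodes.tsv"))
  atac <- readMtx(file.path(dir, "atac.mtx"),
                  file.path(dir, "atac_features.tsv"),
                  file.path(dir, "atac_barcodes.tsv"))
  mm <- readMotifOccurrences(file.path(dir, "motif_occurrences.tsv"),
                             peakIds = names(peaks), pCutoff = scanPCutoff)
  new("HeartStudy",
      donors = donors, cells = cells, genes = genes, peaks = peaks,
      motifMatrix = mm, links = links, rna = rna, atac = atac,
      truth = NULL,
      metadata = list(scan_p_cutoff = scanPCutoff, source = dir))
}
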