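## Differential cell-type composition testing and the covariate-adjusted
## proportion transform used for trend plots.
##
## The independent unit is the donor: repeated (donor, site) samples are
## handled by the beta-binomial mixed model's donor random intercept.

#' Per-sample cell-type counts from cell metadata
#'
#' @param cells data.frame of cells (one modality) with donor_id, site,
#'   age, sex, study, cell_type
#' @return data.frame with one row per (sample, cell type): sample_id,
#'   covariates, cell_type, k (cells of type), n (total cells of sample)
#' @export
cellTypeCounts <- function(cells) {
  .requireColumns(cells, c("donor_id", "site", "age", "sex", "cell_type"),
                  "cell table")
  cells$sample_id <- paste0(cells$donor_id, "_", cells$site)
  samples <- unique(cells[, c("sample_id", "donor_id", "site", "age", "sex",
                              intersect("study", names(cells)))])
  types <- sort(unique(cells$cell_type))
  counts <- table(cells$sample_id, cells$cell_type)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample_id[i]
    k <- as.integer(counts[s, types])
    data.frame(samples[i, , drop = FALSE], cell_type = types, k = k,
               n = sum(k), row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test cell-type proportions against donor covariates
#'
#' One beta-binomial mixed model per cell type (type vs rest), with sex,
#' age and anatomical site as fixed effects and a donor random intercept;
#' \code{meta = TRUE} adds a study fixed effect. Wald z and BH across cell
#' types.
#'
#' @param data output of \code{\link{cellTypeCounts}}
#' @param term tested covariate (\code{"age"} or \code{"sex"})
#' @param meta include the study fixed effect
#' @param fdr BH threshold (default 0.1)
#' @return list with \code{table} (test table across cell types) and
#'   \code{fits} (named per-type \code{FitResult}s)
#' @export
testProportions <- function(data, term = c("age", "sex"), meta = FALSE,
                            fdr = 0.1) {
  term <- match.arg(term)
  .requireColumns(data, c("cell_type", "k", "n", "donor_id", "age", "sex",
                          "site"), "proportion data")
  if (length(unique(data$donor_id)) < 2) {
    stop("mixed model needs >= 2 donors", call. = FALSE)
  }
  fixedTerms <- c("age", "sex", "site")
  if (meta) fixedTerms <- c(fixedTerms, "study")
  types <- sort(unique(data$cell_type))
  fits <- lapply(types, function(t) {
    d <- data[data$cell_type == t, , drop = FALSE]
    fitBetaBinomGlmm(d$k, d$n, d, fixedTerms = fixedTerms)
  })
  names(fits) <- types
  list(table = waldBh(fits, term, fdr), fits = fits)
}

#' Covariate-adjusted proportions
#'
#' Removes named covariate contributions from each sample's observed
#' proportion on the logit scale:
#' adjusted = inverse-logit(logit(k/n) - x_remove' beta_remove).
#' This is the standard "regress out fitted coefficients" transform under a
#' logit link (see the methods vignette for why the one-line formula
#' sometimes printed for this transform is not used verbatim). Samples with
#' k = 0 or k = n get a Haldane-Anscombe 0.5 continuity correction before
#' the logit — a plotting convenience only, never used in fitting.
#'
#' @param data one cell type's rows of \code{\link{cellTypeCounts}} output
#' @param fit the corresponding converged \code{FitResult}
#' @param removeTerms fixed-term names whose contributions are subtracted
#'   (e.g. \code{c("sex", "site", "study")}); must not contain the term
#'   under study and must be a subset of the fitted terms
#' @param protectTerm the term under study (e.g. \code{"age"} when plotting
#'   against age); listing it in \code{removeTerms} is an error
#' @return \code{data} with an \code{adjusted} proportion column in (0, 1)
#' @export
adjustProportions <- function(data, fit, removeTerms, protectTerm = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (!is.null(protectTerm) && protectTerm %in% removeTerms) {
    stop("cannot remove the term under study ('", protectTerm, "')",
         call. = FALSE)
  }
  k <- data$k; n <- data$n
  pObs <- ifelse(k == 0 | k == n, (k + 0.5) / (n + 1), k / n)
  eta <- logit(pObs)
  for (term in removeTerms) {
    co <- fit$coefficients
    hits <- which(co$term == term | startsWith(co$term, term))
    if (length(hits) == 0L) {
      stop("removeTerms contains '", term, "', which is not a fitted term",
           call. = FALSE)
    }
    for (h in hits) {
      cname <- co$term[h]
      x <- if (cname == term) {
        as.numeric(data[[term]])
      } else {
        level <- substring(cname, nchar(term) + 1)
        as.numeric(data[[term]] == level)
      }
      eta <- eta - x * co$estimate[h]
    }
  }
  data$adjusted <- invLogit(eta)
  data
}

#' Predicted proportion-vs-covariate trend with a +/- 2 SE band
#'
#' Predicts the proportion over a covariate grid from the fitted intercept
#' and the covariate's coefficient through the inverse logit; the
#' uncertainty band repeats the prediction with the coefficient moved +/-
#' \code{seBand} standard errors.
#'
#' @param fit a converged \code{FitResult}
#' @param term covariate name (default \code{"age"})
#' @param at numeric grid of covariate values
#' @param seBand half-width of the band in SEs (default 2)
#' @return data.frame with columns \code{term value}, \code{predicted},
#'   \code{lower}, \code{upper}
#' @export
proportionTrend <- function(fit, term = "age", at = seq(25, 70, by = 1),
                            seBand = 2) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  co <- fit$coefficients
  b0 <- co$estimate[co$term == "(Intercept)"]
  row <- coefRow(fit, term)
  if (is.null(row)) stop("term not in fit: ", term, call. = FALSE)
  data.frame(
    value = at,
    predicted = invLogit(b0 + row$estimate * at),
    lower = pmin(invLogit(b0 + (row$estimate - seBand * row$se) * at),
                 invLogit(b0 + (row$estimate + seBand * row$se) * at)),
    upper = pmax(invLogit(b0 + (row$estimate - seBand * row$se) * at),
                 invLogit(b0 + (row$estimate + seBand * row$se) * at))
  )
}
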