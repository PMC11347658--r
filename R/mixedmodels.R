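## Shared estimation engine: negative-binomial and beta-binomial
## regressions with a per-donor random intercept (Laplace-approximated
## marginal likelihood via glmmTMB), Wald z-tests and Benjamini-Hochberg
## correction.
##
## Covariate conventions: `sex` is a factor with baseline F (coefficient
## reported as `sexM`), `site` a factor with baseline LV, `study` a factor
## with the alphabetically first study as baseline, `age` in years,
## `log_depth` = log10 of total UMI. Read depth is controlled as a
## log10(UMI) fixed covariate, matching the meta-analysis design.

#' @noRd
.designFrame <- function(y, covariates, fixedTerms, randomGroup) {
  .requireColumns(covariates, c(fixedTerms, randomGroup), "covariate table")
  df <- covariates[, c(fixedTerms, randomGroup), drop = FALSE]
  df$.y <- y
  if ("sex" %in% fixedTerms) df$sex <- factor(df$sex, levels = c("F", "M"))
  if ("site" %in% fixedTerms) {
    lev <- unique(as.character(df$site))
    lev <- c(intersect("LV", lev), sort(setdiff(lev, "LV")))
    df$site <- factor(df$site, levels = lev)
    if (nlevels(droplevels(df$site)) < 2) {
      df$site <- NULL
      fixedTerms <- setdiff(fixedTerms, "site")
    }
  }
  if ("study" %in% fixedTerms) {
    df$study <- factor(df$study)
    if (nlevels(droplevels(df$study)) < 2) {
      df$study <- NULL
      fixedTerms <- setdiff(fixedTerms, "study")
    }
  }
  df[[randomGroup]] <- factor(df[[randomGroup]])
  if (nlevels(df[[randomGroup]]) < 2) {
    stop("random effect unidentifiable: fewer than 2 donors", call. = FALSE)
  }
  attr(df, "fixedTerms") <- fixedTerms
  df
}

#' @noRd
.fitResult <- function(fit, df, randomGroup, family) {
  sm <- summary(fit)
  co <- sm$coefficients$cond
  ## boundary fits (random-effect variance -> 0, dispersion -> Inf) leave a
  ## non-PD joint Hessian yet give valid fixed-effect estimates; flag
  ## convergence on the optimizer and finite fixed-effect SEs, keep pdHess
  ## as its own field
  conv <- isTRUE(fit$fit$convergence == 0) &&
    all(is.finite(co[, "Std. Error"])) && all(co[, "Std. Error"] > 0)
  vc <- glmmTMB::VarCorr(fit)$cond
  reVar <- if (length(vc) > 0) as.numeric(vc[[randomGroup]][1, 1]) else NA_real_
  disp <- tryCatch(glmmTMB::sigma(fit), error = function(e) NA_real_)
  structure(list(
    coefficients = data.frame(
      term = rownames(co),
      estimate = co[, "Estimate"],
      se = co[, "Std. Error"],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    reVariance = reVar,
    dispersion = disp,
    converged = conv,
    pdHess = isTRUE(fit$sdr$pdHess),
    loglik = as.numeric(logLik(fit)),
    nObs = nrow(df),
    nGroups = nlevels(df[[randomGroup]]),
    family = family
  ), class = "FitResult")
}

#' @noRd
.failedFit <- function(message, nObs = NA_integer_, nGroups = NA_integer_,
                       family = NA_character_) {
  structure(list(
    coefficients = data.frame(term = character(0), estimate = numeric(0),
                              se = numeric(0), stringsAsFactors = FALSE),
    reVariance = NA_real_, dispersion = NA_real_, converged = FALSE,
    loglik = NA_real_, nObs = nObs, nGroups = nGroups, family = family,
    message = message
  ), class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat("FitResult [", x$family, "]",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (nrow(x$coefficients) > 0) print(x$coefficients, digits = 4)
  cat("donor intercept variance:", signif(x$reVariance, 4),
      " dispersion:", signif(x$dispersion, 4),
      " n =", x$nObs, "over", x$nGroups, "donors\n")
  invisible(x)
}

#' Negative-binomial mixed model with a per-donor random intercept
#'
#' Fits counts ~ NB(mean = exp(X beta + b_donor + offset), size theta) with
#' b_donor ~ Normal(0, sigma^2) by Laplace-approximated maximum likelihood.
#' Standard errors come from the observed information; non-convergence is
#' flagged on the returned object rather than raised, so callers can
#' exclude flagged fits from testing.
#'
#' @param y non-negative integer response per cell
#' @param covariates data.frame of per-cell covariates
#' @param fixedTerms covariate names entering as fixed effects
#' @param randomGroup grouping column for the random intercept (donor)
#' @param offset optional log-scale exposure vector
#' @param reml use REML-style integration over fixed effects when
#'   estimating the donor variance (default TRUE): with cohorts of ~8
#'   donors, plain ML underestimates the donor variance by roughly
#'   (G - k)/G and the Wald SEs inherit that bias
#' @return a \code{FitResult}: coefficient table (estimate, se), donor
#'   intercept variance, NB dispersion, convergence flag, log-likelihood
#' @export
fitNbGlmm <- function(y, covariates,
                      fixedTerms = c("age", "sex", "site", "log_depth"),
                      randomGroup = "donor_id", offset = NULL, reml = TRUE) {
  df <- .designFrame(y, covariates, fixedTerms, randomGroup)
  fixedTerms <- attr(df, "fixedTerms")
  if (all(y == 0)) {
    return(.failedFit("all-zero response", nrow(df),
                      nlevels(df[[randomGroup]]), "negbin"))
  }
  fml <- reformulate(c(fixedTerms, sprintf("(1 | %s)", randomGroup)),
                     response = ".y")
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(
      fml, data = df, family = glmmTMB::nbinom2(), offset = offset,
      REML = reml,
      control = glmmTMB::glmmTMBControl(
        optCtrl = list(iter.max = 400, eval.max = 400)))),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(.failedFit(conditionMessage(fit), nrow(df),
                      nlevels(df[[randomGroup]]), "negbin"))
  }
  res <- .fitResult(fit, df, randomGroup, "negbin")
  if (!res$converged && isTRUE(res$dispersion > 1e6)) {
    ## dispersion at the Poisson boundary leaves a singular Hessian; the
    ## model there IS the Poisson GLMM, so refit in the limiting family
    fit2 <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(fml, data = df,
                                        family = stats::poisson(),
                                        offset = offset, REML = reml)),
      error = function(e) e
    )
    if (!inherits(fit2, "error")) {
      res2 <- .fitResult(fit2, df, randomGroup, "negbin (poisson limit)")
      res2$dispersion <- Inf
      if (res2$converged) return(res2)
    }
  }
  res
}

#' Fixed-effects-only negative-binomial GLM (comparison baseline)
#'
#' The same design as \code{\link{fitNbGlmm}} without the donor random
#' intercept. Kept as the comparator that demonstrates why ignoring
#' inter-donor variation inflates false discoveries.
#'
#' @inheritParams fitNbGlmm
#' @return a \code{FitResult}
#' @export
fitNbGlm <- function(y, covariates,
                     fixedTerms = c("age", "sex", "site", "log_depth"),
                     randomGroup = "donor_id", offset = NULL) {
  df <- .designFrame(y, covariates, fixedTerms, randomGroup)
  fixedTerms <- attr(df, "fixedTerms")
  if (all(y == 0)) {
    return(.failedFit("all-zero response", nrow(df),
                      nlevels(df[[randomGroup]]), "negbin-fixed"))
  }
  fml <- reformulate(fixedTerms, response = ".y")
  if (!is.null(offset)) {
    df$.off <- offset
    fml <- update(fml, . ~ . + offset(.off))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = df)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(.failedFit(conditionMessage(fit), nrow(df),
                      nlevels(df[[randomGroup]]), "negbin-fixed"))
  }
  co <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], row.names = NULL,
                              stringsAsFactors = FALSE),
    reVariance = 0, dispersion = fit$theta,
    converged = isTRUE(fit$converged),
    loglik = as.numeric(logLik(fit)),
    nObs = nrow(df), nGroups = nlevels(df[[randomGroup]]),
    family = "negbin-fixed"
  ), class = "FitResult")
}

#' Beta-binomial mixed model with a per-donor random intercept
#'
#' Logit-link beta-binomial regression of per-sample success counts with a
#' donor random intercept, Laplace-approximated likelihood, SEs from the
#' observed information. Degenerate inputs (k identically 0 or identically
#' n) are flagged as non-converged rather than fit.
#'
#' @param k successes per sample (cells of the type under test)
#' @param n totals per sample
#' @param covariates data.frame of per-sample covariates
#' @inheritParams fitNbGlmm
#' @return a \code{FitResult}
#' @export
fitBetaBinomGlmm <- function(k, n, covariates,
                             fixedTerms = c("age", "sex", "site"),
                             randomGroup = "donor_id", reml = TRUE) {
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  df <- .designFrame(k, covariates, fixedTerms, randomGroup)
  fixedTerms <- attr(df, "fixedTerms")
  df$.n <- n
  if (all(k == 0) || all(k == n)) {
    return(.failedFit("degenerate response (complete separation)",
                      nrow(df), nlevels(df[[randomGroup]]), "betabinom"))
  }
  fml <- reformulate(c(fixedTerms, sprintf("(1 | %s)", randomGroup)),
                     response = "cbind(.y, .n - .y)")
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(
      fml, data = df, family = glmmTMB::betabinomial(), REML = reml)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(.failedFit(conditionMessage(fit), nrow(df),
                      nlevels(df[[randomGroup]]), "betabinom"))
  }
  res <- .fitResult(fit, df, randomGroup, "betabinom")
  if (!res$converged && isTRUE(res$dispersion > 1e4)) {
    ## beta-binomial dispersion at the binomial boundary: refit as the
    ## limiting binomial GLMM (identical model there) for usable SEs
    fit2 <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(fml, data = df,
                                        family = stats::binomial(),
                                        REML = reml)),
      error = function(e) e
    )
    if (!inherits(fit2, "error")) {
      res2 <- .fitResult(fit2, df, randomGroup, "betabinom (binomial limit)")
      res2$dispersion <- Inf
      if (res2$converged) return(res2)
    }
  }
  res
}

#' Extract one term's coefficient row from a FitResult
#'
#' Matches the exact coefficient name first, then a unique factor expansion
#' (e.g. term \code{"sex"} matches \code{"sexM"}).
#'
#' @param fit a \code{FitResult}
#' @param term covariate name
#' @return one-row data.frame (term, estimate, se) or NULL if absent
#' @export
coefRow <- function(fit, term) {
  co <- fit$coefficients
  hit <- which(co$term == term)
  if (length(hit) == 0L) hit <- which(startsWith(co$term, term))
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L) {
    stop("term '", term, "' matches several coefficients: ",
         paste(co$term[hit], collapse = ", "), call. = FALSE)
  }
  co[hit, , drop = FALSE]
}

#' Wald z-tests with Benjamini-Hochberg correction over a feature family
#'
#' For every converged fit, z = estimate / SE and p = 2 * Phi(-|z|); q-values
#' come from the BH step-up procedure applied within the supplied family
#' (typically one cell type x one term x one analysis). Non-converged fits
#' are excluded from testing.
#'
#' @param fits named list of \code{FitResult}s (names = feature ids)
#' @param term covariate whose coefficient is tested
#' @param fdr significance threshold on q (default 0.1)
#' @return a test-table data.frame: feature, term, estimate, se, z, p, q,
#'   significant, n_obs, n_groups
#' @export
waldBh <- function(fits, term, fdr = 0.1) {
  .assertScalarNumber(fdr, "fdr", 0, 1)
  if (length(fits) == 0L) {
    return(data.frame(feature = character(0), term = character(0),
                      estimate = numeric(0), se = numeric(0), z = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0),
                      n_obs = integer(0), n_groups = integer(0)))
  }
  rows <- lapply(names(fits), function(f) {
    fit <- fits[[f]]
    if (!isTRUE(fit$converged)) return(NULL)
    co <- coefRow(fit, term)
    if (is.null(co) || !is.finite(co$se) || co$se <= 0) return(NULL)
    data.frame(feature = f, term = co$term, estimate = co$estimate,
               se = co$se, z = co$estimate / co$se,
               n_obs = fit$nObs, n_groups = fit$nGroups,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(waldBh(list(), term, fdr))
  }
  tab$p <- 2 * pnorm(-abs(tab$z))
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < fdr
  tab <- tab[, c("feature", "term", "estimate", "se", "z", "p", "q",
                 "significant", "n_obs", "n_groups")]
  rownames(tab) <- NULL
  attr(tab, "fdr") <- fdr
  tab
}
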