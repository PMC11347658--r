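## Direct simulation from the NB GLMM (independent of the study generator)
simulateNbData <- function(nDonors = 8, cellsPerDonor = 120, betaSex = 0,
                           sigma = 0.5, theta = 2, baseline = 1, seed = 1) {
  withr::local_seed(seed)
  donors <- sprintf("d%02d", seq_len(nDonors))
  sex <- rep(c("F", "M"), length.out = nDonors)
  re <- rnorm(nDonors, 0, sigma)
  df <- data.frame(
    donor_id = rep(donors, each = cellsPerDonor),
    sex = rep(sex, each = cellsPerDonor),
    age = rep(round(runif(nDonors, 25, 70), 1), each = cellsPerDonor),
    site = sample(c("LV", "RV"), nDonors * cellsPerDonor, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df$log_depth <- rnorm(nrow(df), 3, 0.15)
  mu <- exp(log(baseline) + betaSex * (df$sex == "M") +
              rep(re, each = cellsPerDonor) +
              log(10) * (df$log_depth - 3))
  df$y <- rnbinom(nrow(df), mu = mu, size = theta)
  df
}

test_that("NB mixed model recovers a planted sex effect", {
  df <- simulateNbData(betaSex = 0.5, seed = 42)
  fit <- fitNbGlmm(df$y, df)
  expect_true(fit$converged)
  row <- coefRow(fit, "sex")
  expect_lt(abs(row$estimate - 0.5), 2 * row$se)
  expect_gt(fit$reVariance, 0.02)
  expect_lt(abs(fit$dispersion - 2), 1.2)
})

test_that("with no donor variation the mixed fit reduces to the fixed GLM", {
  df <- simulateNbData(nDonors = 6, cellsPerDonor = 250, betaSex = 0.4,
                       sigma = 0, seed = 9)
  mixed <- fitNbGlmm(df$y, df)
  fixed <- fitNbGlm(df$y, df)
  expect_true(mixed$converged && fixed$converged)
  m <- coefRow(mixed, "sex"); f <- coefRow(fixed, "sex")
  expect_lt(abs(m$estimate - f$estimate) / max(abs(f$estimate), 1e-6), 1e-3)
  expect_lt(abs(coefRow(mixed, "log_depth")$estimate -
                coefRow(fixed, "log_depth")$estimate) /
              abs(coefRow(fixed, "log_depth")$estimate), 1e-3)
})

test_that("degenerate responses are flagged, never reported as significant", {
  df <- simulateNbData(seed = 3)
  zero <- fitNbGlmm(rep(0L, nrow(df)), df)
  expect_false(zero$converged)
  tab <- waldBh(list(f = zero), "sex")
  expect_equal(nrow(tab), 0)

  expect_error(fitNbGlmm(df$y, transform(df, donor_id = "d01")),
               "fewer than 2 donors")
})

simulateBbData <- function(nDonors = 20, beta = 0, sigmaRe = 0.4, rho = 0.02,
                           n = 200, seed = 1) {
  withr::local_seed(seed)
  donors <- sprintf("d%02d", seq_len(nDonors))
  df <- do.call(rbind, lapply(seq_len(nDonors), function(i) {
    data.frame(donor_id = donors[i],
               sex = c("F", "M")[1 + i %% 2],
               age = round(runif(1, 25, 70), 1),
               site = c("LV", "RV"), stringsAsFactors = FALSE)
  }))
  re <- rnorm(nDonors, 0, sigmaRe)
  eta <- -1.5 + beta * (df$sex == "M") + re[match(df$donor_id, donors)]
  p <- plogis(eta)
  if (rho > 0) {
    shp <- (1 - rho) / rho
    p <- rbeta(nrow(df), p * shp, (1 - p) * shp)
  }
  df$n <- n
  df$k <- rbinom(nrow(df), n, p)
  df
}

test_that("beta-binomial mixed model recovers a planted logit sex effect", {
  df <- simulateBbData(nDonors = 30, beta = 1, seed = 21)
  fit <- fitBetaBinomGlmm(df$k, df$n, df)
  expect_true(fit$converged)
  row <- coefRow(fit, "sex")
  expect_lt(abs(row$estimate - 1), 2 * row$se)
})

test_that("beta-binomial fit matches logistic regression in the binomial limit", {
  df <- simulateBbData(nDonors = 30, beta = 0.8, sigmaRe = 0, rho = 0,
                       n = 400, seed = 5)
  fit <- fitBetaBinomGlmm(df$k, df$n, df)
  expect_true(fit$converged)
  glm0 <- glm(cbind(k, n - k) ~ age + sex + site, binomial(), data = df)
  b <- coef(glm0)[["sexM"]]
  expect_lt(abs(coefRow(fit, "sex")$estimate - b) / abs(b), 1e-3)
})

test_that("complete separation in proportions is flagged", {
  df <- simulateBbData(nDonors = 6, seed = 2)
  allN <- fitBetaBinomGlmm(df$n, df$n, df)
  expect_false(allN$converged)
  expect_error(fitBetaBinomGlmm(df$k + df$n, df$n, df), "0 <= k <= n")
})

test_that("Wald z-tests and BH correction behave as the textbook procedure", {
  mkFit <- function(est, se) manualFit(c("(Intercept)", "sexM"),
                                       c(0, est), c(0.1, se))
  tab <- waldBh(list(a = mkFit(1.959964, 1)), "sex", fdr = 0.1)
  expect_equal(tab$p, 0.05, tolerance = 1e-6)

  fits <- list(f1 = mkFit(2.5758, 1), f2 = mkFit(2.3263, 1),
               f3 = mkFit(2.1701, 1), f4 = mkFit(0.2533, 1))
  tab <- waldBh(fits, "sex")
  ## hand-computed BH on p = (0.01, 0.02, 0.03, 0.8)
  expect_equal(tab$q, c(0.04, 0.04, 0.04, 0.8), tolerance = 1e-3)
  expect_true(all(tab$q >= tab$p - 1e-12))

  ## BH equals the brute-force step-up formula on random p-vectors
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bruteBH(p))
  }

  expect_equal(nrow(waldBh(list(), "sex")), 0)
})

test_that("null features yield uniform p-values and no BH discoveries", {
  set.seed(123)
  fits <- lapply(1:200, function(i) {
    manualFit(c("(Intercept)", "sexM"), c(0, rnorm(1)), c(0.1, 1))
  })
  names(fits) <- sprintf("f%03d", 1:200)
  tab <- waldBh(fits, "sex")
  expect_lt(abs(mean(tab$p < 0.05) - 0.05), 0.04)
  expect_lte(sum(tab$q < 0.1), 1)
})
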