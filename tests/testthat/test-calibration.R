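# Random-intercept fitting, AICc, R2 decomposition, likelihood-ratio
# tests and expenditure prediction.

test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-50, 2, 10), 100 + 4 + 12 / 7)
  expect_equal(aicc(-50, 2, 10), 105.7142857, tolerance = 1e-7)
  # converges to AIC for large n
  expect_lt(abs(aicc(-50, 3, 1e6) - (100 + 6)), 1e-4)
  # strictly increasing in k at fixed log-likelihood
  ks <- 1:6
  vals <- vapply(ks, function(k) aicc(-50, k, 30), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(-50, 9, 10), "nObs")
})

test_that("R2 decomposition follows the variance-components formula", {
  r2 <- r2Nakagawa(c(2, 1, 1))
  expect_equal(unname(r2), c(0.5, 0.75))
  # no random-intercept variance: marginal equals conditional
  r2b <- r2Nakagawa(c(2, 0, 1))
  expect_equal(r2b[["r2m"]], r2b[["r2c"]])
  expect_error(r2Nakagawa(c(0, 0, 0)), "variance")
})

test_that("null models have zero marginal R2 and r2m <= r2c always", {
  d <- simulateCalibrationDataset(mixedModelSpec(seed = 31))
  null <- fitRandomIntercept(d, character(0), "mr")
  expect_equal(null@r2m, 0, tolerance = 1e-10)
  for (p in list("fh", "tb", c("fh", "tb"))) {
    f <- fitRandomIntercept(d, p, "mr")
    expect_lte(f@r2m, f@r2c + 1e-12)
    expect_lte(f@r2c, 1)
  }
})

test_that("noise-free data recover the generating line exactly", {
  d <- simulateCalibrationDataset(
    mixedModelSpec(sigmaIndividual = 0, sigmaResidual = 0, seed = 3))
  f <- fitRandomIntercept(d, "fh", "mr")
  expect_equal(f@beta[["fh"]], 0.00106, tolerance = 1e-8)
  expect_equal(f@beta[["(Intercept)"]], 0.0527, tolerance = 1e-8)
})

test_that("with identical individuals the fit reduces to ordinary least squares", {
  set.seed(17)
  d <- data.frame(individual = factor(rep(c("a", "b"), each = 100)))
  d$fh <- runif(200, 60, 900)
  d$mr <- 0.05 + 0.001 * d$fh + rnorm(200, 0, 0.02)   # no individual effect
  f <- fitRandomIntercept(d, "fh", "mr")
  ols <- lm(mr ~ fh, data = d)
  expect_equal(f@beta[["fh"]], coef(ols)[["fh"]], tolerance = 1e-4)
  expect_equal(f@beta[["(Intercept)"]], coef(ols)[["(Intercept)"]],
               tolerance = 1e-3)
})

test_that("likelihood-ratio tests behave at the identity and under strong effects", {
  d <- simulateCalibrationDataset(mixedModelSpec(seed = 41))
  f1 <- fitRandomIntercept(d, "fh", "mr")
  same <- lrTest(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  null <- fitRandomIntercept(d, character(0), "mr")
  lt <- lrTest(null, f1)
  expect_equal(lt$df, 1)
  expect_gt(lt$chi2, 100)
  expect_lt(lt$p, 0.001)
  # chi2 = 3.84 on 1 df sits at the 5 percent point
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 0.001)
  f2 <- fitRandomIntercept(d, "tb", "mr")
  expect_error(lrTest(f2, f1), "not nested")
})

test_that("model selection ranks by AICc with deterministic tie-breaks", {
  d <- simulateCalibrationDataset(mixedModelSpec(seed = 51))
  sel <- modelSelection(d, list("fh", "fh", "tb"))
  # duplicate candidates: identical AICc, adjacent in the ranking
  expect_equal(sel$table$aicc[1L], sel$table$aicc[2L])
  expect_equal(sel$table$daicc[1L], 0)
  # ranking is invariant to row order
  sel2 <- modelSelection(d[sample(nrow(d)), ], list("fh", "fh", "tb"))
  expect_equal(sel2$table$model, sel$table$model)
  expect_equal(sel2$table$aicc, sel$table$aicc, tolerance = 1e-6)
})

test_that("delta-AICc is invariant to affine rescaling of the response", {
  d <- simulateCalibrationDataset(mixedModelSpec(seed = 61))
  cands <- list("fh", "tb", "tdiff")
  s1 <- modelSelection(d, cands)
  d2 <- d
  d2$mr <- 3.6 * d2$mr + 5
  s2 <- modelSelection(d2, cands)
  expect_equal(s1$table$model, s2$table$model)
  expect_equal(s1$table$daicc, s2$table$daicc, tolerance = 1e-4)
})

test_that("Wald intervals for the slope show near-nominal coverage", {
  hits <- 0
  nRep <- 100
  for (i in seq_len(nRep)) {
    d <- simulateCalibrationDataset(mixedModelSpec(seed = 5000 + i))
    f <- fitRandomIntercept(d, "fh", "mr")
    se <- sqrt(diag(as.matrix(vcov(f@fit))))[2L]
    ci <- f@beta[["fh"]] + c(-1.96, 1.96) * se
    if (ci[1L] <= 0.00106 && 0.00106 <= ci[2L]) hits <- hits + 1
  }
  expect_gte(hits / nRep, 0.90)
  expect_lte(hits / nRep, 0.99)
})

test_that("expenditure prediction is linear with an enforced unit tag", {
  cc <- calibrationCoefficients(unit = "kJ/d")
  expect_equal(as.numeric(predictExpenditure(0, cc)), 0.0527)
  expect_equal(as.numeric(predictExpenditure(100, cc)), 0.1587)
  expect_identical(attr(predictExpenditure(0, cc), "unit"), "kJ/d")
  a <- 120; b <- 250
  expect_equal(predictExpenditure(a, cc) + predictExpenditure(b, cc) -
                 predictExpenditure(0, cc),
               predictExpenditure(a + b, cc))
  expect_error(predictExpenditure(100, cc, unit = "kJ/h"), "mismatch")
  expect_error(predictExpenditure(-5, cc), "non-negative")
  expect_error(calibrationCoefficients(), "unit")
})
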