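# Statistical core: random-intercept linear models of metabolic rate on
# heart rate and temperature predictors, AICc ranking,
# Nakagawa-Schielzeth R2, likelihood-ratio tests, and prediction of
# energy expenditure from heart rate.

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik model log-likelihood.
#' @param kParams number of estimated parameters (here: fixed effects
#'   plus the random-intercept and residual variances).
#' @param nObs number of observations; must exceed `kParams + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-50, 2, 10)   # 105.7143
#' @export
aicc <- function(loglik, kParams, nObs) {
  if (nObs <= kParams + 1)
    stop("AICc requires nObs > kParams + 1")
  -2 * loglik + 2 * kParams + 2 * kParams * (kParams + 1) / (nObs - kParams - 1)
}

#' Fit a random-intercept linear model
#'
#' Fits `response ~ predictors + (1 | individual)` by maximum
#' likelihood (default; REML likelihoods are not comparable across
#' fixed-effect structures, so ML is required whenever fits will be
#' ranked by AICc). The response is continuous, so the mixed model is
#' linear with identity link. The parameter count for AICc is the
#' number of fixed effects plus two variance components. A singular fit
#' (random-intercept variance estimated at zero) is returned with the
#' `singular` flag set, not as an error.
#'
#' @param data data.frame with an `individual` column (>= 2 levels),
#'   the response and the predictors. Rows with missing values in the
#'   used columns are dropped listwise; the per-fit `nObs` records the
#'   rows actually used.
#' @param predictors character vector of predictor terms (e.g.
#'   `c("fh")`, `c("fh", "tb")`, `c("fh", "fh:tb")`); empty for the
#'   intercept-only null model.
#' @param response response column name.
#' @param method `"ML"` (default) or `"REML"` (variance reporting only).
#' @param unit unit tag carried to predictions (taken from
#'   `attr(data, "unit")` when present).
#' @return A [ModelFit].
#' @export
fitRandomIntercept <- function(data, predictors = "fh", response = "mr",
                               method = c("ML", "REML"),
                               unit = attr(data, "unit")) {
  method <- match.arg(method)
  if (is.null(unit)) unit <- NA_character_
  if (!"individual" %in% names(data))
    stop("data must contain an 'individual' column")
  vars <- unique(unlist(strsplit(predictors, ":", fixed = TRUE)))
  used <- c(response, vars, "individual")
  used <- used[used %in% names(data)]
  data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  if (length(unique(data$individual)) < 2L)
    stop("need at least 2 individuals for a random-intercept fit")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  form <- as.formula(paste(response, "~", rhs, "+ (1 | individual)"))
  fit <- lme4::lmer(form, data = data, REML = (method == "REML"),
                    control = lme4::lmerControl(
                      calc.derivs = FALSE,
                      check.scaleX = "ignore"))  # bpm vs kJ/h scales differ by design
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigmaU <- vc$sdcor[vc$grp == "individual"][1L]
  sigmaE <- vc$sdcor[vc$grp == "Residual"][1L]
  ll <- as.numeric(logLik(fit))
  n <- nrow(data)
  k <- length(beta) + 2
  varF <- var(as.vector(model.matrix(fit) %*% beta))
  r2 <- .r2FromVariances(varF, sigmaU^2, sigmaE^2)
  new("ModelFit",
      formula = paste(response, "~", rhs, "+ (1 | individual)"),
      predictors = as.character(predictors), beta = beta,
      sigmaU = sigmaU, sigmaE = sigmaE, loglik = ll, nObs = n,
      kParams = k, aicc = aicc(ll, k, n), r2m = unname(r2[1L]),
      r2c = unname(r2[2L]),
      fitMethod = method, singular = lme4::isSingular(fit),
      unit = as.character(unit), fit = fit)
}

.r2FromVariances <- function(varFixed, varRandom, varResidual) {
  tot <- varFixed + varRandom + varResidual
  if (tot <= 0) stop("zero total variance: R2 undefined")
  c(r2m = varFixed / tot, r2c = (varFixed + varRandom) / tot)
}

#' Marginal and conditional R-squared for a random-intercept fit
#'
#' Variance-components decomposition: the marginal R2 is the variance
#' of the fixed-effect linear predictor over the data divided by the
#' total (fixed + random-intercept + residual) variance; the
#' conditional R2 adds the random-intercept variance to the numerator.
#' `r2m <= r2c` always, with equality exactly when the random-intercept
#' variance is zero.
#'
#' @param fit a [ModelFit], or a numeric vector of the three variance
#'   components `c(fixed, random, residual)`.
#' @return Named vector `c(r2m, r2c)`.
#' @examples
#' r2Nakagawa(c(2, 1, 1))   # r2m 0.5, r2c 0.75
#' @export
r2Nakagawa <- function(fit) {
  if (is.numeric(fit) && length(fit) == 3L)
    return(.r2FromVariances(fit[1L], fit[2L], fit[3L]))
  stopifnot(is(fit, "ModelFit"))
  c(r2m = fit@r2m, r2c = fit@r2c)
}

#' Fit and rank candidate models by AICc
#'
#' Fits every candidate predictor set by ML on the identical
#' listwise-complete rows (the union of all candidate variables
#' determines completeness) and ranks by AICc, ties broken by fewer
#' parameters. Candidates that fail to fit are recorded as failed and
#' excluded from the ranking order, and the ranking proceeds.
#'
#' @param data as for [fitRandomIntercept()].
#' @param candidates list of character vectors of predictor terms.
#'   `NULL` uses the default set: each of `fh`, `tb`, `tdiff` alone,
#'   all pairs, and the `fh x temperature` interactions.
#' @param response response column name.
#' @return A list with `table` (data.frame: model, k, AICc, dAICc, R2m,
#'   R2c, n, singular, failed; ranked) and `fits` (the [ModelFit]
#'   objects, in table order).
#' @export
modelSelection <- function(data, candidates = NULL, response = "mr") {
  if (is.null(candidates))
    candidates <- list("fh", "tb", "tdiff",
                       c("fh", "tb"), c("fh", "tdiff"), c("tb", "tdiff"),
                       c("fh", "tb", "fh:tb"), c("fh", "tdiff", "fh:tdiff"))
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  vars <- unique(unlist(strsplit(unlist(candidates), ":", fixed = TRUE)))
  vars <- vars[vars %in% names(data)]
  keep <- complete.cases(data[, c(response, vars, "individual"),
                              drop = FALSE])
  data <- data[keep, , drop = FALSE]
  fits <- lapply(candidates, function(p) {
    tryCatch(fitRandomIntercept(data, p, response, "ML"),
             error = function(e) e)
  })
  label <- vapply(candidates, paste, character(1), collapse = " + ")
  failed <- vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    model = label,
    k = vapply(fits, function(f) if (is(f, "ModelFit")) f@kParams else NA_real_,
               numeric(1)),
    aicc = vapply(fits, function(f) if (is(f, "ModelFit")) f@aicc else NA_real_,
                  numeric(1)),
    r2m = vapply(fits, function(f) if (is(f, "ModelFit")) f@r2m else NA_real_,
                 numeric(1)),
    r2c = vapply(fits, function(f) if (is(f, "ModelFit")) f@r2c else NA_real_,
                 numeric(1)),
    n = vapply(fits, function(f) if (is(f, "ModelFit")) f@nObs else NA_real_,
               numeric(1)),
    singular = vapply(fits, function(f)
      if (is(f, "ModelFit")) f@singular else NA, logical(1)),
    failed = failed)
  ord <- order(tab$aicc, tab$k, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$daicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  rownames(tab) <- NULL
  list(table = tab, fits = fits[ord])
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi2 = 2 (logLik_full - logLik_nested) with degrees of freedom equal
#' to the parameter difference. Both fits must be ML fits of the same
#' response on the same rows, with the nested model's predictors a
#' subset of the full model's. Testing a variance component on its
#' boundary (sigma_u = 0) makes the chi2 reference conservative; this
#' function is intended for fixed-effect comparisons.
#'
#' @param nested,full [ModelFit] objects.
#' @return A list with `chi2`, `df`, `p`.
#' @export
lrTest <- function(nested, full) {
  stopifnot(is(nested, "ModelFit"), is(full, "ModelFit"))
  if (!all(nested@predictors %in% full@predictors))
    stop("models are not nested: nested predictors must be a subset")
  if (nested@fitMethod != "ML" || full@fitMethod != "ML")
    stop("likelihood-ratio tests require ML fits")
  if (nested@nObs != full@nObs)
    stop("fits use different numbers of rows")
  df <- full@kParams - nested@kParams
  chi2 <- max(0, 2 * (full@loglik - nested@loglik))
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 <= 1e-8)
  list(chi2 = chi2, df = df, p = p)
}

#' Calibration coefficients for predicting expenditure from heart rate
#'
#' Bundles a linear heart-rate calibration
#' `expenditure = intercept + slope * f_H` with an explicit unit tag.
#' The defaults are the fitted calibration for *Molossus molossus*
#' (slope 0.00106, intercept 0.0527); the unit must be chosen
#' explicitly because the published equation is labelled kJ d-1 while
#' its numerical range matches the kJ h-1 measurements — no silent
#' conversion is ever applied.
#'
#' @param intercept,slope linear coefficients.
#' @param unit `"kJ/d"` or `"kJ/h"` (any string is carried verbatim).
#' @return An object of class `"calibCoefficients"`.
#' @export
calibrationCoefficients <- function(intercept = 0.0527, slope = 0.00106,
                                    unit) {
  if (missing(unit))
    stop("choose the unit explicitly (\"kJ/d\" or \"kJ/h\"): the ",
         "published calibration is unit-ambiguous")
  structure(list(intercept = intercept, slope = slope, unit = unit),
            class = "calibCoefficients")
}

#' Predict energy expenditure from heart rate
#'
#' Population-level linear prediction (random intercept at zero) from a
#' fitted model or a coefficient bundle. The unit tag of the
#' calibration is propagated; when the caller states an expected unit
#' that differs from the fit's, an error is raised rather than a
#' conversion applied.
#'
#' @param fh heart rate(s), bpm, non-negative.
#' @param fit a [ModelFit] with an `fh` coefficient, or a
#'   [calibrationCoefficients()] bundle.
#' @param unit optional expected unit; must match the fit's tag.
#' @return Predicted expenditure, with the unit as `attr(, "unit")`.
#' @examples
#' cc <- calibrationCoefficients(unit = "kJ/d")
#' predictExpenditure(100, cc)   # 0.1587
#' @export
predictExpenditure <- function(fh, fit, unit = NULL) {
  if (any(fh < 0)) stop("fh must be non-negative")
  if (inherits(fit, "calibCoefficients")) {
    b0 <- fit$intercept
    b1 <- fit$slope
    fitUnit <- fit$unit
  } else if (is(fit, "ModelFit")) {
    if (!"fh" %in% names(fit@beta))
      stop("fit has no heart-rate coefficient")
    b0 <- fit@beta[["(Intercept)"]]
    b1 <- fit@beta[["fh"]]
    fitUnit <- fit@unit
  } else stop("fit must be a ModelFit or calibrationCoefficients")
  if (!is.null(unit) && !is.na(fitUnit) && unit != fitUnit)
    stop("unit mismatch: fit is in ", fitUnit, ", requested ", unit)
  out <- b0 + b1 * fh
  attr(out, "unit") <- fitUnit
  out
}
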