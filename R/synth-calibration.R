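# Calibration-dataset generator: random-intercept linear data with
# known coefficients, plus companion temperature columns so the full
# candidate-model set is fittable.

#' Simulate a calibration dataset from a random-intercept linear model
#'
#' Draws `y_ij = intercept + slope * x_ij + u_i + e_ij` with
#' `u_i ~ N(0, sigmaIndividual^2)`, `e_ij ~ N(0, sigmaResidual^2)` and
#' `x` uniform over `xRange`. When the predictor is heart rate (`"fh"`),
#' companion `tb`, `ta` and `tdiff` columns are generated: body
#' temperature rises linearly with heart rate over the observed
#' 27.9--37.6 degrees C span (with 1.5 degrees C scatter), the chamber
#' temperature is drawn from 28/32 degrees C, and `tdiff = tb - ta`.
#' These give the temperature-based candidate models realistic,
#' fH-correlated but less informative predictors.
#'
#' @param spec a [mixedModelSpec()].
#' @param seed integer seed overriding `spec@seed`; `NA` uses `spec@seed`.
#' @return A data.frame with columns `individual` (factor), the
#'   predictor and response columns named per the spec, and (for the
#'   `"fh"` predictor) `tb`, `ta`, `tdiff`. The response unit tag is
#'   attached as `attr(, "unit")`.
#' @examples
#' d <- simulateCalibrationDataset(mixedModelSpec(seed = 1))
#' head(d)
#' @export
simulateCalibrationDataset <- function(spec, seed = NA_real_) {
  stopifnot(is(spec, "MixedModelSpec"))
  if (is.na(seed)) seed <- spec@seed
  if (!is.na(seed)) set.seed(as.integer(seed))
  nInd <- as.integer(spec@nIndividuals)
  nObs <- as.integer(spec@nObsPerIndividual)
  individual <- factor(rep(sprintf("ind%02d", seq_len(nInd)), each = nObs))
  x <- runif(nInd * nObs, spec@xRange[1L], spec@xRange[2L])
  u <- rnorm(nInd, 0, spec@sigmaIndividual)[as.integer(individual)]
  e <- rnorm(nInd * nObs, 0, spec@sigmaResidual)
  y <- spec@intercept + spec@slope * x + u + e
  out <- data.frame(individual = individual)
  out[[spec@predictor]] <- x
  if (spec@predictor == "fh") {
    frac <- (x - spec@xRange[1L]) / diff(spec@xRange)
    tb <- 27.9 + 9.7 * frac + rnorm(length(x), 0, 1.5)
    ta <- sample(c(28, 32), length(x), replace = TRUE)
    out$tb <- tb
    out$ta <- ta
    out$tdiff <- tb - ta
  }
  out[[spec@response]] <- y
  attr(out, "unit") <- spec@unit
  out
}
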