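# Shared fixtures, built in code.

cleanAudio <- function(bpm, seconds = 10, fs = 48000, noiseSd = 0,
                       seed = 1, ...) {
  synthesizeTransmitterAudio(
    signalSpec(sampleRate = fs, noiseSd = noiseSd, seed = seed, ...),
    constantRate(bpm, seconds))
}

# true positives: ground-truth beats matched by a detection within tol
matchedBeats <- function(truth, detected, tol) {
  sum(vapply(truth, function(b) any(abs(detected - b) < tol), logical(1)))
}

# records table for field regressions with known slopes:
# tb = 0.481 ta + c + u_i + e ; fh = 14.985 tb - 353.237 + u_i + e
fieldRegressionData <- function(seed, nInd = 6, nObs = 150) {
  set.seed(seed)
  individual <- factor(rep(sprintf("i%02d", seq_len(nInd)), each = nObs))
  ta <- runif(nInd * nObs, 22, 29)
  uTb <- rnorm(nInd, 0, 1)[as.integer(individual)]
  tb <- 17 + 0.481 * ta + uTb + rnorm(nInd * nObs, 0, 1.2)
  uFh <- rnorm(nInd, 0, 15)[as.integer(individual)]
  fh <- -353.237 + 14.985 * tb + uFh + rnorm(nInd * nObs, 0, 20)
  data.frame(individual = individual, ta = ta, tb = tb, fh = fh,
             tdiff = tb - ta)
}
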