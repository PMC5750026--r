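# Forward respirometry model: invert the gas-exchange equations so that
# a prescribed metabolic-rate trajectory produces excurrent fractions
# which the analysis path recovers exactly in the noise-free case.

.defaultBaselineSchedule <- function(duration, baselineLen = 300,
                                     period = 1800) {
  starts <- seq(0, duration - baselineLen, by = period)
  if (max(starts) < duration - baselineLen)
    starts <- c(starts, duration - baselineLen)
  lapply(starts, function(s) c(s, s + baselineLen))
}

.inBaseline <- function(time, schedule) {
  mask <- rep(FALSE, length(time))
  for (p in schedule) mask <- mask | (time >= p[1] & time < p[2])
  mask
}

#' Simulate an open-flow respirometry trace
#'
#' Forward model of the push-through system: the metabolic-rate
#' trajectory (kJ h-1) is converted to a target CO2 production via the
#' 25.0 J ml-1 CO2 equivalence, excurrent CO2 is obtained by inverting
#' the gas-exchange equation (the same "printed" form the analysis path
#' evaluates, see [computeVCO2()]), and excurrent O2 by inverting the
#' CO2-scrubbed O2 equation at `vo2 = vco2 / rer`. During baseline
#' periods the analyzers see the empty reference chamber, i.e. the
#' incurrent fractions. Analyzer drift (linear, fraction per hour) and
#' Gaussian noise are added to the measured excurrent channels.
#'
#' @param chamber a [chamberSpec()].
#' @param mrTraj metabolic-rate trajectory: a data.frame with columns
#'   `time` (s) and `mr_kj_h`, linearly interpolated, or a single
#'   non-negative number.
#' @param rer respiratory exchange ratio in (0.7, 1].
#' @param duration total duration in seconds.
#' @param chamberTemp chamber temperature (scalar or per-sample).
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return A [RespirometryTrace].
#' @export
simulateRespirometryTrace <- function(chamber, mrTraj, rer = 0.8,
                                      duration = 7200, chamberTemp = 28,
                                      seed = NA_real_) {
  stopifnot(is(chamber, "ChamberSpec"))
  if (rer <= 0.7 || rer > 1) stop("rer must lie in (0.7, 1]")
  if (!is.na(seed)) set.seed(as.integer(seed))
  time <- seq(0, duration, by = chamber@sampleInterval)
  if (is.numeric(mrTraj) && length(mrTraj) == 1L) {
    mr <- rep(mrTraj, length(time))
  } else {
    mr <- approx(mrTraj$time, mrTraj$mr_kj_h, xout = time, rule = 2)$y
  }
  if (any(mr < 0)) stop("metabolic-rate trajectory must be non-negative")

  schedule <- chamber@baselineSchedule
  if (!length(schedule)) schedule <- .defaultBaselineSchedule(duration)
  baseline <- .inBaseline(time, schedule)

  vco2 <- mr * 1000 / 25 / 60                      # ml min-1
  vo2 <- vco2 / rer
  fr <- chamber@flowRate
  fi <- chamber@incurrentCo2
  fio2 <- chamber@incurrentO2
  # inverse of the printed equation: vco2 = (Fe - Fi) FR / (1 - Fe RER)
  feco2 <- (vco2 + fi * fr) / (fr + vco2 * rer)
  # inverse of vo2 = FR (FiO2 - FeO2) / (1 - FiO2)
  feo2 <- fio2 - vo2 * (1 - fio2) / fr

  feco2[baseline] <- fi
  feo2[baseline] <- fio2
  drift <- chamber@driftSlope * time / 3600
  feco2 <- feco2 + drift
  feo2 <- feo2 + drift
  if (chamber@noiseSd > 0) {
    feco2 <- feco2 + rnorm(length(time), 0, chamber@noiseSd)
    feo2 <- feo2 + rnorm(length(time), 0, chamber@noiseSd)
  }
  respirometryTrace(time = time,
                    feco2 = pmin(pmax(feco2, 0), 1), fico2 = fi,
                    feo2 = pmin(pmax(feo2, 0), 1), fio2 = fio2,
                    flowRate = fr, chamberTemp = chamberTemp, rh = 5,
                    baselineMask = baseline)
}

#' Simulate a two-temperature respirometry protocol
#'
#' Emulates the measurement protocol for a thermoconforming bat: the
#' chamber is held at each ambient temperature for `blockHours` in
#' alternation, the animal sits at a temperature-specific resting
#' metabolic plateau with slow Ornstein-Uhlenbeck fluctuation, and
#' brief arousal excursions are superimposed at random times. Default
#' plateau means are 0.131 kJ h-1 at 28 degrees C and 0.160 kJ h-1 at
#' 32 degrees C with a within-state s.d. of 0.019 kJ h-1, the steady
#' resting condition observed for *Molossus molossus*.
#'
#' @param taLevels ambient temperatures, degrees C.
#' @param mrLevels resting metabolic-rate plateau per temperature, kJ h-1.
#' @param mrSd slow within-plateau fluctuation s.d., kJ h-1.
#' @param blockHours hours per temperature block.
#' @param nBlocks total number of blocks (alternating over `taLevels`).
#' @param arousalsPerBlock expected arousal excursions per block.
#' @param arousalPeak peak arousal MR, kJ h-1.
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return A list with `mrTraj` (data.frame `time`, `mr_kj_h`), `ta`
#'   (data.frame `time`, `ta`), and `stateTa` (the scheduled temperature
#'   for every trajectory point).
#' @export
simulateMetabolicProtocol <- function(taLevels = c(28, 32),
                                      mrLevels = c(0.131, 0.160),
                                      mrSd = 0.019, blockHours = 3,
                                      nBlocks = 4, arousalsPerBlock = 1,
                                      arousalPeak = 1.0,
                                      seed = NA_real_) {
  stopifnot(length(taLevels) == length(mrLevels))
  if (!is.na(seed)) set.seed(as.integer(seed))
  dt <- 60                                          # 1-min resolution
  blockLen <- blockHours * 3600
  duration <- nBlocks * blockLen
  time <- seq(0, duration - dt, by = dt)
  blockIdx <- pmin(floor(time / blockLen) + 1L, nBlocks)
  levelIdx <- ((blockIdx - 1L) %% length(taLevels)) + 1L
  ta <- taLevels[levelIdx]
  mu <- mrLevels[levelIdx]

  # OU fluctuation around the plateau, ~20-min correlation time
  theta <- 1 / (20 * 60)
  z <- numeric(length(time))
  z[1L] <- rnorm(1, 0, mrSd)
  sdStep <- mrSd * sqrt(1 - exp(-2 * theta * dt))
  phi <- exp(-theta * dt)
  for (i in seq_along(time)[-1L]) z[i] <- phi * z[i - 1L] + rnorm(1, 0, sdStep)
  mr <- mu + z

  nArousal <- rpois(1, arousalsPerBlock * nBlocks)
  if (nArousal > 0) {
    starts <- runif(nArousal, 0, duration - 900)
    for (s in starts) {
      sel <- time >= s & time < s + 900
      shape <- exp(-((time[sel] - s - 300) / 180)^2)
      mr[sel] <- mr[sel] + (arousalPeak - mu[sel]) * pmax(shape, 0)
    }
  }
  mr <- pmax(mr, 0.02)
  list(mrTraj = data.frame(time = time, mr_kj_h = mr),
       ta = data.frame(time = time, ta = ta),
       stateTa = ta)
}
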