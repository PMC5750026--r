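# S4 containers for the telemetry-energetics pipeline. Parameter bundles
# (the *Spec classes) validate their invariants on construction; data
# containers validate structural consistency (lengths, ordering, ranges).

#' @rdname AudioRecording
#' @export
setClass("AudioRecording",
  slots = c(samples = "numeric", sampleRate = "numeric",
            startTime = "numeric"),
  prototype = prototype(samples = numeric(0), sampleRate = 48000,
                        startTime = 0))

setValidity("AudioRecording", function(object) {
  msg <- character(0)
  if (length(object@samples) < 1L) msg <- c(msg, "samples must be non-empty")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (anyNA(object@samples)) msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Sampled single-channel audio of a heart-rate transmitter signal
#'
#' A continuous carrier tone interrupted by cardiac muscle potentials,
#' as emitted by externally mounted heart-rate transmitters and recorded
#' from a telemetry receiver to a wave file.
#'
#' @param samples numeric vector of amplitudes.
#' @param sampleRate sampling rate in Hz.
#' @param startTime recording start, seconds (offset of the first sample).
#' @return An `AudioRecording` object.
#' @examples
#' a <- audioRecording(sin(2 * pi * 1500 * (0:999) / 48000), 48000)
#' duration(a)
#' @export
audioRecording <- function(samples, sampleRate, startTime = 0) {
  new("AudioRecording", samples = as.numeric(samples),
      sampleRate = sampleRate, startTime = startTime)
}

#' @rdname rateTrajectory
#' @export
setClass("RateTrajectory",
  slots = c(breakpoints = "numeric", rates = "numeric",
            interpolation = "character", duration = "numeric"))

setValidity("RateTrajectory", function(object) {
  msg <- character(0)
  if (length(object@breakpoints) != length(object@rates))
    msg <- c(msg, "breakpoints and rates must have equal length")
  if (length(object@breakpoints) < 1L || object@breakpoints[1L] != 0)
    msg <- c(msg, "breakpoints must start at 0")
  if (any(diff(object@breakpoints) <= 0))
    msg <- c(msg, "breakpoints must be strictly increasing")
  if (any(object@rates < 0 | object@rates > 1200))
    msg <- c(msg, "rates must lie within [0, 1200] bpm")
  if (length(object@duration) != 1L || object@duration <= 0 ||
      object@duration < max(object@breakpoints))
    msg <- c(msg, "duration must be positive and cover all breakpoints")
  if (!object@interpolation %in% c("step", "linear"))
    msg <- c(msg, "interpolation must be 'step' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' Piecewise heart-rate trajectory
#'
#' Describes a true heart-rate course in beats per minute as a piecewise
#' (step or linear) function of time, used as ground truth by the audio
#' synthesizer. Rates are restricted to 0--1200 bpm, a generous envelope
#' around the 58--1068 bpm range observed in small bats.
#'
#' @param breakpoints segment start times in seconds; must begin at 0 and
#'   increase strictly.
#' @param rates bpm value attached to each breakpoint. Under `"step"`
#'   interpolation `rates[i]` holds on `[breakpoints[i], breakpoints[i+1])`;
#'   under `"linear"` the rate is interpolated between breakpoints and held
#'   constant after the last one.
#' @param duration total duration in seconds.
#' @param interpolation `"step"` or `"linear"`.
#' @return A `RateTrajectory`.
#' @examples
#' constantRate(120, 60)
#' stepRate(c(0, 30), c(100, 600), 60)
#' @export
rateTrajectory <- function(breakpoints, rates, duration = max(breakpoints),
                           interpolation = c("step", "linear")) {
  interpolation <- match.arg(interpolation)
  new("RateTrajectory", breakpoints = as.numeric(breakpoints),
      rates = as.numeric(rates), interpolation = interpolation,
      duration = as.numeric(duration))
}

#' @rdname rateTrajectory
#' @param bpm constant rate in beats per minute.
#' @export
constantRate <- function(bpm, duration) {
  rateTrajectory(0, bpm, duration, "step")
}

#' @rdname rateTrajectory
#' @param times breakpoint times (must start at 0).
#' @export
stepRate <- function(times, rates, duration = max(times)) {
  rateTrajectory(times, rates, duration, "step")
}

#' @rdname signalSpec
#' @export
setClass("SignalSpec",
  slots = c(sampleRate = "numeric", carrierFreq = "numeric",
            beatPulseWidth = "numeric", beatDepth = "numeric",
            noiseSd = "numeric", staticBurstRate = "numeric",
            edgeFraction = "numeric", seed = "numeric"))

setValidity("SignalSpec", function(object) {
  msg <- character(0)
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (object@carrierFreq <= 0 || object@carrierFreq >= object@sampleRate / 2)
    msg <- c(msg, "carrierFreq must lie in (0, sampleRate/2)")
  if (object@beatPulseWidth <= 0)
    msg <- c(msg, "beatPulseWidth must be positive")
  if (object@beatDepth <= 0 || object@beatDepth > 1)
    msg <- c(msg, "beatDepth must lie in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@staticBurstRate < 0)
    msg <- c(msg, "staticBurstRate must be non-negative")
  if (object@edgeFraction < 0 || object@edgeFraction >= 0.5)
    msg <- c(msg, "edgeFraction must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Transmitter audio synthesis parameters
#'
#' Parameters of the synthetic transmitter signal: a sine carrier whose
#' amplitude is suppressed for `beatPulseWidth` seconds at every
#' heartbeat (a rectangular gate with optional raised-cosine edges),
#' plus Gaussian noise and optional Poisson-timed wide-band static
#' bursts emulating radio interference.
#'
#' The default sampling rate of 48 kHz yields 96 non-overlapping
#' 500-sample counting windows per second in the detector; 44.1 kHz
#' yields 88.2, spanning the 88--96 windows-per-second operating range
#' of the original scoring setup.
#'
#' @param sampleRate Hz.
#' @param carrierFreq carrier tone frequency, Hz; must be below Nyquist.
#' @param beatPulseWidth seconds of carrier suppression per beat.
#' @param beatDepth fraction of carrier amplitude suppressed, in (0, 1].
#' @param noiseSd additive Gaussian noise s.d. (amplitude units; carrier
#'   amplitude is 1).
#' @param staticBurstRate wide-band static bursts per minute.
#' @param edgeFraction fraction of the pulse width used for each
#'   raised-cosine edge (0 gives a pure rectangle).
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return A `SignalSpec`.
#' @export
signalSpec <- function(sampleRate = 48000, carrierFreq = 1500,
                       beatPulseWidth = 0.015, beatDepth = 0.9,
                       noiseSd = 0.05, staticBurstRate = 0,
                       edgeFraction = 0.2, seed = NA_real_) {
  new("SignalSpec", sampleRate = sampleRate, carrierFreq = carrierFreq,
      beatPulseWidth = beatPulseWidth, beatDepth = beatDepth,
      noiseSd = noiseSd, staticBurstRate = staticBurstRate,
      edgeFraction = edgeFraction, seed = as.numeric(seed))
}

#' @rdname chamberSpec
#' @export
setClass("ChamberSpec",
  slots = c(flowRate = "numeric", incurrentCo2 = "numeric",
            incurrentO2 = "numeric", baselineSchedule = "list",
            driftSlope = "numeric", noiseSd = "numeric",
            sampleInterval = "numeric"))

setValidity("ChamberSpec", function(object) {
  msg <- character(0)
  if (object@flowRate <= 0) msg <- c(msg, "flowRate must be positive")
  if (object@incurrentCo2 < 0 || object@incurrentCo2 > 1 ||
      object@incurrentO2 < 0 || object@incurrentO2 > 1)
    msg <- c(msg, "incurrent fractions must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be positive")
  ok <- vapply(object@baselineSchedule, function(p)
    is.numeric(p) && length(p) == 2L && p[2L] > p[1L], logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "baselineSchedule entries must be c(start, end) with end > start")
  if (length(msg)) msg else TRUE
})

#' Respirometry chamber and analyzer parameters
#'
#' Describes the open-flow push-through setup used for the forward
#' simulation: a dried-air stream of `flowRate` ml min-1 through the
#' animal chamber, with an empty reference chamber sampled during the
#' periods in `baselineSchedule`. `driftSlope` adds a linear analyzer
#' drift (fraction units per hour) to all measured excurrent channels,
#' which baseline correction is expected to remove.
#'
#' @param flowRate STP-corrected flow in ml min-1 (default 300).
#' @param incurrentCo2,incurrentO2 incurrent fractional concentrations.
#' @param baselineSchedule list of `c(start, end)` reference periods in
#'   seconds; `NULL` asks the simulator to insert 5-min baselines at the
#'   start and end and every 30 min in between.
#' @param driftSlope analyzer drift, fraction per hour.
#' @param noiseSd Gaussian measurement noise s.d., fraction units.
#' @param sampleInterval analyzer sampling interval, seconds (1 Hz default).
#' @return A `ChamberSpec`.
#' @export
chamberSpec <- function(flowRate = 300, incurrentCo2 = 4e-4,
                        incurrentO2 = 0.2095, baselineSchedule = NULL,
                        driftSlope = 0, noiseSd = 0, sampleInterval = 1) {
  if (is.null(baselineSchedule)) baselineSchedule <- list()
  new("ChamberSpec", flowRate = flowRate, incurrentCo2 = incurrentCo2,
      incurrentO2 = incurrentO2, baselineSchedule = baselineSchedule,
      driftSlope = driftSlope, noiseSd = noiseSd,
      sampleInterval = sampleInterval)
}

#' @rdname thermalSpec
#' @export
setClass("ThermalSpec",
  slots = c(kCool = "numeric", heatGain = "numeric", tbInit = "numeric"))

setValidity("ThermalSpec", function(object) {
  msg <- character(0)
  if (object@kCool <= 0) msg <- c(msg, "kCool must be positive")
  if (object@heatGain < 0) msg <- c(msg, "heatGain must be non-negative")
  if (length(msg)) msg else TRUE
})

#' First-order body-temperature dynamics parameters
#'
#' Body temperature relaxes toward the ambient temperature plus a
#' metabolic heat offset: dTb/dt = kCool (Ta + heatGain * MR - Tb).
#' This encodes the observed lag of body temperature behind metabolic
#' state: heart rate (and MR) drop quickly into a low-energy state while
#' Tb follows at a slower, exponential rate.
#'
#' @param kCool relaxation constant, per minute (default 0.03, i.e. a
#'   ~33-min time constant).
#' @param heatGain equilibrium temperature elevation per unit MR,
#'   degrees C per (kJ h-1).
#' @param tbInit initial body temperature, degrees C.
#' @return A `ThermalSpec`.
#' @export
thermalSpec <- function(kCool = 0.03, heatGain = 40, tbInit = 34) {
  new("ThermalSpec", kCool = kCool, heatGain = heatGain, tbInit = tbInit)
}

#' @rdname mixedModelSpec
#' @export
setClass("MixedModelSpec",
  slots = c(intercept = "numeric", slope = "numeric",
            sigmaIndividual = "numeric", sigmaResidual = "numeric",
            nIndividuals = "numeric", nObsPerIndividual = "numeric",
            xRange = "numeric", predictor = "character",
            response = "character", unit = "character", seed = "numeric"))

setValidity("MixedModelSpec", function(object) {
  msg <- character(0)
  if (object@sigmaIndividual < 0 || object@sigmaResidual < 0)
    msg <- c(msg, "sigmas must be non-negative")
  if (object@nIndividuals < 2) msg <- c(msg, "nIndividuals must be >= 2")
  if (object@nObsPerIndividual < 2)
    msg <- c(msg, "nObsPerIndividual must be >= 2")
  if (length(object@xRange) != 2L || diff(object@xRange) <= 0)
    msg <- c(msg, "xRange must be c(min, max) with max > min")
  if (length(msg)) msg else TRUE
})

#' Random-intercept linear data-generating parameters
#'
#' Generating model `y_ij = intercept + slope * x_ij + u_i + e_ij` with
#' `u_i ~ N(0, sigmaIndividual^2)` and `e_ij ~ N(0, sigmaResidual^2)`,
#' `x` drawn uniformly over `xRange`. Defaults reproduce the fitted
#' heart-rate calibration for *Molossus molossus*
#' (expenditure = 0.00106 f_H + 0.0527) over the observed 59--999 bpm
#' heart-rate range, with variance components sized so the implied
#' conditional R-squared is 0.88.
#'
#' @param intercept,slope fixed-effect coefficients.
#' @param sigmaIndividual s.d. of per-individual random intercepts.
#' @param sigmaResidual residual s.d.
#' @param nIndividuals,nObsPerIndividual design size.
#' @param xRange range of the uniform predictor draw.
#' @param predictor,response column names for the generated data.
#' @param unit unit tag carried on the response (`"kJ/d"` follows the
#'   printed calibration equation; `"kJ/h"` available).
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return A `MixedModelSpec`.
#' @export
mixedModelSpec <- function(intercept = 0.0527, slope = 0.00106,
                           sigmaIndividual = 0.05, sigmaResidual = 0.108,
                           nIndividuals = 6, nObsPerIndividual = 150,
                           xRange = c(59, 999), predictor = "fh",
                           response = "mr", unit = "kJ/d",
                           seed = NA_real_) {
  new("MixedModelSpec", intercept = intercept, slope = slope,
      sigmaIndividual = sigmaIndividual, sigmaResidual = sigmaResidual,
      nIndividuals = nIndividuals, nObsPerIndividual = nObsPerIndividual,
      xRange = as.numeric(xRange), predictor = predictor,
      response = response, unit = unit, seed = as.numeric(seed))
}

#' @rdname detectionConfig
#' @export
setClass("DetectionConfig",
  slots = c(firLength = "numeric", bandHalfwidth = "numeric",
            windowLen = "numeric", envelopeThreshold = "numeric",
            refractory = "numeric", kdeQuantile = "numeric",
            kdeBandwidth = "ANY", kdeMethod = "character",
            envelopeSmooth = "numeric", carrierSpan = "numeric",
            minEventDuration = "numeric", silenceFloor = "numeric",
            searchBand = "numeric", carrierMargin = "numeric"))

setValidity("DetectionConfig", function(object) {
  msg <- character(0)
  if (object@firLength < 3) msg <- c(msg, "firLength must be >= 3")
  if (object@windowLen < 1) msg <- c(msg, "windowLen must be >= 1")
  if (object@kdeQuantile <= 0 || object@kdeQuantile >= 1)
    msg <- c(msg, "kdeQuantile must lie in (0, 1)")
  if (object@refractory < 0) msg <- c(msg, "refractory must be >= 0")
  if (object@envelopeThreshold <= 0 || object@envelopeThreshold >= 1)
    msg <- c(msg, "envelopeThreshold must lie in (0, 1)")
  if (!object@kdeMethod %in% c("hdr", "interval"))
    msg <- c(msg, "kdeMethod must be 'hdr' or 'interval'")
  if (length(msg)) msg else TRUE
})

#' Heartbeat-detection configuration
#'
#' Tunable parameters of the automated scoring chain. The FIR length
#' default sits in the 1500--2000-sample range used for carrier
#' selection; counting runs over non-overlapping `windowLen`-sample
#' windows (500 samples, i.e. 88--96 windows per second at common
#' recorder rates). A beat is an envelope excursion below
#' `envelopeThreshold` times the local (rolling-median) carrier
#' amplitude; the transmitter gates its carrier off at each cardiac
#' potential, so detection is on downward excursions. The kernel-density
#' filter discards rate values outside the `kdeQuantile`
#' highest-density region (`kdeMethod = "hdr"`, default) or outside the
#' central value interval (`"interval"`).
#'
#' @param firLength FIR filter length in samples (1500--2000 typical).
#' @param bandHalfwidth half-width of the pass band around the carrier, Hz.
#' @param windowLen counting-window length in samples.
#' @param envelopeThreshold fraction of the rolling carrier amplitude
#'   below which the envelope counts as interrupted.
#' @param refractory minimum separation of successive beats, seconds.
#'   The 40-ms default caps the detectable rate at 1500 bpm, above the
#'   1068 bpm field maximum.
#' @param kdeQuantile retained density mass for the KDE filter.
#' @param kdeBandwidth `"silverman"` or a numeric bandwidth in bpm.
#' @param kdeMethod `"hdr"` or `"interval"`.
#' @param envelopeSmooth RMS-envelope smoothing window, seconds.
#' @param carrierSpan rolling-median span for the local carrier
#'   amplitude, seconds.
#' @param minEventDuration shortest envelope excursion accepted as a
#'   beat, seconds.
#' @param silenceFloor median-envelope level below which a recording is
#'   treated as carrier-free (flagged, zero counts).
#' @param searchBand carrier search band in Hz; `NA` upper bound means
#'   90 percent of Nyquist.
#' @param carrierMargin required ratio of the spectral peak over the
#'   in-band median power before a carrier is accepted.
#' @return A `DetectionConfig`.
#' @export
detectionConfig <- function(firLength = 1500, bandHalfwidth = 200,
                            windowLen = 500, envelopeThreshold = 0.5,
                            refractory = 0.04, kdeQuantile = 0.90,
                            kdeBandwidth = "silverman",
                            kdeMethod = c("hdr", "interval"),
                            envelopeSmooth = 0.002, carrierSpan = 2,
                            minEventDuration = 0.004,
                            silenceFloor = 1e-3,
                            searchBand = c(200, NA), carrierMargin = 30) {
  kdeMethod <- match.arg(kdeMethod)
  new("DetectionConfig", firLength = firLength,
      bandHalfwidth = bandHalfwidth, windowLen = windowLen,
      envelopeThreshold = envelopeThreshold, refractory = refractory,
      kdeQuantile = kdeQuantile, kdeBandwidth = kdeBandwidth,
      kdeMethod = kdeMethod, envelopeSmooth = envelopeSmooth,
      carrierSpan = carrierSpan, minEventDuration = minEventDuration,
      silenceFloor = silenceFloor, searchBand = as.numeric(searchBand),
      carrierMargin = carrierMargin)
}

#' @rdname BeatEvents
#' @export
setClass("BeatEvents",
  slots = c(eventTimes = "numeric", windowCounts = "integer",
            windowTimes = "numeric", windowLen = "numeric",
            sampleRate = "numeric", flags = "character"))

setValidity("BeatEvents", function(object) {
  msg <- character(0)
  if (length(object@windowCounts) != length(object@windowTimes))
    msg <- c(msg, "windowCounts and windowTimes must have equal length")
  if (any(object@windowCounts < 0)) msg <- c(msg, "counts must be >= 0")
  if (is.unsorted(object@eventTimes))
    msg <- c(msg, "eventTimes must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Detected heartbeat events and per-window counts
#'
#' Event times (seconds, on the recording's time base) together with the
#' tally of events per non-overlapping counting window. The window
#' resolution in windows per second is `sampleRate / windowLen`.
#' `flags` carries quality warnings such as `"silent"`.
#'
#' @name BeatEvents
#' @aliases BeatEvents-class
NULL

#' @rdname HeartRateSeries
#' @export
setClass("HeartRateSeries",
  slots = c(time = "numeric", bpm = "numeric", quality = "character"))

setValidity("HeartRateSeries", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@bpm) != n || length(object@quality) != n)
    msg <- c(msg, "time, bpm and quality must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (any(object@bpm < 0, na.rm = TRUE)) msg <- c(msg, "bpm must be >= 0")
  if (!all(object@quality %in% c("raw", "filtered-out", "interpolated")))
    msg <- c(msg, "quality must be raw | filtered-out | interpolated")
  if (length(msg)) msg else TRUE
})

#' Timestamped heart-rate series with quality flags
#'
#' Beats-per-minute values on a strictly increasing time axis. Each
#' value carries a quality flag: `"raw"` (direct count), `"filtered-out"`
#' (rejected by the kernel-density filter), or `"interpolated"`
#' (derived, e.g. a trailing-window smooth).
#'
#' @param time seconds, strictly increasing.
#' @param bpm heart rate values (NA allowed).
#' @param quality per-value flag; recycled if length 1.
#' @return A `HeartRateSeries`.
#' @export
heartRateSeries <- function(time, bpm, quality = "raw") {
  if (length(quality) == 1L) quality <- rep(quality, length(time))
  new("HeartRateSeries", time = as.numeric(time), bpm = as.numeric(bpm),
      quality = quality)
}

#' @rdname RespirometryTrace
#' @export
setClass("RespirometryTrace",
  slots = c(time = "numeric", feco2 = "numeric", fico2 = "numeric",
            feo2 = "numeric", fio2 = "numeric", flowRate = "numeric",
            chamberTemp = "numeric", rh = "numeric",
            baselineMask = "logical", corrected = "logical"))

setValidity("RespirometryTrace", function(object) {
  msg <- character(0)
  n <- length(object@time)
  lens <- c(length(object@feco2), length(object@fico2),
            length(object@feo2), length(object@fio2),
            length(object@flowRate), length(object@chamberTemp),
            length(object@rh), length(object@baselineMask))
  if (!all(lens == n)) msg <- c(msg, "all channels must match time length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  frac <- c(object@feco2, object@fico2, object@feo2, object@fio2)
  if (any(frac < 0 | frac > 1, na.rm = TRUE))
    msg <- c(msg, "gas fractions must lie in [0, 1]")
  if (any(object@flowRate <= 0)) msg <- c(msg, "flowRate must be positive")
  if (length(msg)) msg else TRUE
})

#' Raw open-flow respirometry trace
#'
#' Time-stamped excurrent/incurrent CO2 and O2 fractions, flow rate,
#' chamber temperature and relative humidity, with a logical mask
#' marking reference (empty-chamber baseline) periods. `corrected`
#' records whether [baselineCorrect()] has been applied.
#'
#' @param time seconds, strictly increasing.
#' @param feco2,fico2 excurrent and incurrent CO2 fractions.
#' @param feo2,fio2 excurrent and incurrent O2 fractions.
#' @param flowRate STP-corrected flow, ml min-1 (recycled if scalar).
#' @param chamberTemp chamber temperature, degrees C.
#' @param rh relative humidity, percent.
#' @param baselineMask logical; TRUE during reference periods.
#' @return A `RespirometryTrace`.
#' @export
respirometryTrace <- function(time, feco2, fico2, feo2, fio2,
                              flowRate = 300, chamberTemp = 28, rh = 5,
                              baselineMask = FALSE) {
  n <- length(time)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  new("RespirometryTrace", time = as.numeric(time), feco2 = rec(feco2),
      fico2 = rec(fico2), feo2 = rec(feo2), fio2 = rec(fio2),
      flowRate = rec(flowRate), chamberTemp = rec(chamberTemp),
      rh = rec(rh), baselineMask = rec(baselineMask), corrected = FALSE)
}

#' @rdname MetabolicSeries
#' @export
setClass("MetabolicSeries",
  slots = c(time = "numeric", vco2 = "numeric", vo2 = "numeric",
            mrKjH = "numeric", mrWg = "numeric", massG = "numeric"))

setValidity("MetabolicSeries", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@vco2) != n || length(object@mrKjH) != n ||
      length(object@vo2) != n || length(object@mrWg) != n)
    msg <- c(msg, "all series must match time length")
  if (length(object@massG) != 1L || object@massG <= 0)
    msg <- c(msg, "massG must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Metabolic-rate series derived from gas exchange
#'
#' CO2 production and O2 consumption rates (ml min-1) plus the derived
#' metabolic rate in kJ h-1 and, mass-specifically, W g-1.
#'
#' @name MetabolicSeries
#' @aliases MetabolicSeries-class
NULL

#' @rdname ModelFit
#' @export
setClass("ModelFit",
  slots = c(formula = "character", predictors = "character",
            beta = "numeric", sigmaU = "numeric", sigmaE = "numeric",
            loglik = "numeric", nObs = "numeric", kParams = "numeric",
            aicc = "numeric", r2m = "numeric", r2c = "numeric",
            fitMethod = "character", singular = "logical",
            unit = "character", fit = "ANY"))

setValidity("ModelFit", function(object) {
  msg <- character(0)
  if (object@sigmaU < 0 || object@sigmaE < 0)
    msg <- c(msg, "variance components must be non-negative")
  if (is.finite(object@r2m) && is.finite(object@r2c) &&
      (object@r2m > object@r2c + 1e-10 || object@r2c > 1 + 1e-10))
    msg <- c(msg, "must satisfy r2m <= r2c <= 1")
  if (length(msg)) msg else TRUE
})

#' Fitted random-intercept linear model
#'
#' One candidate model of metabolic rate (or another response) on
#' heart-rate/temperature predictors: fixed-effect coefficients,
#' random-intercept and residual standard deviations, log-likelihood,
#' AICc, and Nakagawa-Schielzeth marginal/conditional R-squared. The
#' underlying `lmerMod` object is retained in the `fit` slot.
#'
#' @name ModelFit
#' @aliases ModelFit-class
NULL
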