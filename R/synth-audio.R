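# Transmitter-audio forward model: deterministic beat placement by
# inversion of the integrated rate trajectory, carrier synthesis, and
# stochastic noise/static overlays.

# Piecewise segments of a trajectory: start, end, startRate, endRate.
.trajSegments <- function(traj) {
  bp <- traj@breakpoints
  r <- traj@rates
  n <- length(bp)
  starts <- bp
  ends <- c(bp[-1L], traj@duration)
  if (traj@interpolation == "step") {
    r0 <- r
    r1 <- r
  } else {
    r0 <- r
    r1 <- c(r[-1L], r[n])
  }
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep],
             r0 = r0[keep], r1 = r1[keep])
}

#' Evaluate a rate trajectory
#'
#' @param traj a [rateTrajectory()].
#' @param t times in seconds.
#' @return `rateAt`: bpm at each time. `cumulativeBeats`: the expected
#'   (fractional) number of beats in `[0, t]`, i.e. the integral of the
#'   rate over time divided by 60.
#' @export
rateAt <- function(traj, t) {
  stopifnot(is(traj, "RateTrajectory"))
  if (traj@interpolation == "step") {
    idx <- findInterval(t, traj@breakpoints, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    traj@rates[idx]
  } else {
    approx(traj@breakpoints, traj@rates, xout = t, rule = 2)$y
  }
}

#' @rdname rateAt
#' @export
cumulativeBeats <- function(traj, t) {
  stopifnot(is(traj, "RateTrajectory"))
  seg <- .trajSegments(traj)
  segBeats <- (seg$r0 + seg$r1) / 2 * (seg$end - seg$start) / 60
  cumStart <- c(0, cumsum(segBeats))
  vapply(t, function(ti) {
    ti <- min(max(ti, 0), traj@duration)
    i <- findInterval(ti, seg$start)
    if (i < 1L) return(0)
    dt <- ti - seg$start[i]
    slope <- (seg$r1[i] - seg$r0[i]) / (seg$end[i] - seg$start[i])
    cumStart[i] + (seg$r0[i] * dt + slope * dt^2 / 2) / 60
  }, numeric(1))
}

# Deterministic beat times: the k-th beat falls where the cumulative
# beat count crosses k - 1/2 (midpoint convention, so no pulse sits on
# the recording boundary). Solved analytically per segment (linear or
# quadratic cumulative), so counts over any interval match the rate
# integral to within one beat.
.beatTimesFromTrajectory <- function(traj) {
  seg <- .trajSegments(traj)
  out <- numeric(0)
  cum <- 0
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    slope <- (seg$r1[i] - seg$r0[i]) / len
    segTotal <- (seg$r0[i] + seg$r1[i]) / 2 * len / 60
    kmin <- ceiling(cum + 0.5 + 1e-12)
    kmax <- floor(cum + segTotal + 0.5 + 1e-12)
    ks <- if (kmax >= kmin) (kmin:kmax) - 0.5 else numeric(0)
    if (length(ks)) {
      dN <- (ks - cum) * 60
      if (abs(slope) < 1e-12) {
        dt <- dN / seg$r0[i]
      } else {
        disc <- seg$r0[i]^2 + 2 * slope * dN
        dt <- (-seg$r0[i] + sqrt(pmax(disc, 0))) / slope
      }
      out <- c(out, seg$start[i] + dt)
    }
    cum <- cum + segTotal
  }
  out
}

#' Synthesize transmitter audio with known heartbeat ground truth
#'
#' Produces the received audio of a carrier-interruption heart-rate
#' transmitter: a sine carrier of unit amplitude, suppressed by
#' `beatDepth` for `beatPulseWidth` seconds at every heartbeat, with
#' additive Gaussian noise and optional Poisson-timed wide-band static
#' bursts. Beat times are placed deterministically where the integral
#' of the rate trajectory crosses successive whole beats, so the
#' ground-truth count over any interval matches the analytic rate
#' integral to within one beat.
#'
#' @param spec a [signalSpec()].
#' @param traj a [rateTrajectory()] giving the true heart-rate course.
#' @return A list with `audio` (an [AudioRecording]) and `beatTimes`
#'   (numeric seconds, the ground truth).
#' @examples
#' out <- synthesizeTransmitterAudio(signalSpec(sampleRate = 8000,
#'                                              noiseSd = 0, seed = 1),
#'                                   constantRate(120, 10))
#' length(out$beatTimes)
#' @export
synthesizeTransmitterAudio <- function(spec, traj) {
  stopifnot(is(spec, "SignalSpec"), is(traj, "RateTrajectory"))
  maxRate <- max(traj@rates)
  if (spec@beatPulseWidth * maxRate / 60 >= 1)
    stop("beat pulses would overlap: beatPulseWidth * max rate / 60 ",
         "must be < 1 (got ",
         signif(spec@beatPulseWidth * maxRate / 60, 3), ")")
  if (!is.na(spec@seed)) set.seed(as.integer(spec@seed))
  fs <- spec@sampleRate
  n <- round(traj@duration * fs)
  t <- (seq_len(n) - 1) / fs
  beats <- .beatTimesFromTrajectory(traj)

  envelope <- rep(1, n)
  widthSamp <- max(1L, round(spec@beatPulseWidth * fs))
  edgeSamp <- round(spec@edgeFraction * widthSamp)
  gate <- rep(1, widthSamp)
  if (edgeSamp > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edgeSamp) / edgeSamp))
    gate[seq_len(edgeSamp)] <- ramp
    gate[widthSamp + 1L - seq_len(edgeSamp)] <- ramp
  }
  for (b in beats) {
    i0 <- floor(b * fs) + 1L
    idx <- i0:min(i0 + widthSamp - 1L, n)
    if (i0 <= n)
      envelope[idx] <- envelope[idx] * (1 - spec@beatDepth * gate[seq_along(idx)])
  }

  x <- envelope * sin(2 * pi * spec@carrierFreq * t)
  if (spec@noiseSd > 0) x <- x + rnorm(n, 0, spec@noiseSd)
  if (spec@staticBurstRate > 0) {
    nBurst <- rpois(1, spec@staticBurstRate * traj@duration / 60)
    if (nBurst > 0) {
      starts <- sort(runif(nBurst, 0, traj@duration))
      burstSamp <- max(1L, round(0.02 * fs))
      for (s in starts) {
        i0 <- floor(s * fs) + 1L
        idx <- i0:min(i0 + burstSamp - 1L, n)
        x[idx] <- x[idx] + rnorm(length(idx), 0, 0.8)
      }
    }
  }
  list(audio = audioRecording(x, fs), beatTimes = beats)
}
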