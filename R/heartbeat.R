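# Automated heartbeat scoring: band-limit the recording to the
# transmitter carrier, detect carrier interruptions on the amplitude
# envelope, tally events over non-overlapping 500-sample windows,
# convert to bpm, and reject noisy rate values with a kernel-density
# quantile filter.

.movingMean <- function(x, k) {
  if (k <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # fill filter edges with the nearest computed value
  firstOk <- which(!is.na(y))[1L]
  lastOk <- max(which(!is.na(y)))
  y[seq_len(firstOk - 1L)] <- y[firstOk]
  if (lastOk < length(y)) y[(lastOk + 1L):length(y)] <- y[lastOk]
  y
}

#' Estimate the transmitter carrier frequency
#'
#' Welch-averaged periodogram over the configured search band; the
#' dominant peak is accepted as the carrier only if it exceeds the
#' in-band median power by `carrierMargin`, otherwise a "no carrier"
#' error is raised (a flat spectrum means the transmitter is out of
#' range or the recording is noise).
#'
#' @param audio an [AudioRecording] of at least 1 s.
#' @param config a [detectionConfig()].
#' @return The carrier frequency in Hz.
#' @export
estimateCarrierFrequency <- function(audio, config = detectionConfig()) {
  stopifnot(is(audio, "AudioRecording"))
  fs <- sampleRate(audio)
  x <- audioSamples(audio)
  if (length(x) < fs) stop("recording must be at least 1 s long")
  segLen <- min(2^floor(log2(length(x))), 65536L)
  nSeg <- min(length(x) %/% segLen, 8L)
  pxx <- 0
  for (i in seq_len(nSeg)) {
    seg <- x[((i - 1L) * segLen + 1L):(i * segLen)]
    seg <- seg - mean(seg)
    pxx <- pxx + Mod(fft(seg)[seq_len(segLen %/% 2L)])^2
  }
  freqs <- (seq_len(segLen %/% 2L) - 1L) * fs / segLen
  hi <- config@searchBand[2L]
  if (is.na(hi)) hi <- 0.9 * fs / 2
  inBand <- freqs >= config@searchBand[1L] & freqs <= hi
  if (!any(inBand)) stop("search band is empty at this sample rate")
  p <- pxx[inBand]
  f <- freqs[inBand]
  peak <- which.max(p)
  if (!is.finite(p[peak]) || p[peak] <= 0 ||
      p[peak] < config@carrierMargin * median(p))
    stop("no carrier: spectral peak does not rise above the noise floor")
  f[peak]
}

#' Band-pass filter a recording around the carrier
#'
#' Linear-phase FIR band-pass (Hamming-windowed, `firLength` taps,
#' half-width `bandHalfwidth` around `center`), applied by FFT
#' convolution with the group delay compensated so event times are not
#' shifted. Pass-band gain is within 1 dB of unity at the center
#' frequency for the default 1500--2000-tap lengths.
#'
#' @param audio an [AudioRecording].
#' @param center pass-band center frequency, Hz.
#' @param config a [detectionConfig()].
#' @return A filtered [AudioRecording] on the same time base.
#' @export
bandpassFilter <- function(audio, center, config = detectionConfig()) {
  stopifnot(is(audio, "AudioRecording"))
  fs <- sampleRate(audio)
  lo <- center - config@bandHalfwidth
  hi <- center + config@bandHalfwidth
  if (lo <= 0 || hi >= fs / 2)
    stop("pass band [", lo, ", ", hi, "] Hz falls outside (0, Nyquist)")
  taps <- as.integer(config@firLength)
  if (taps %% 2L == 0L) taps <- taps + 1L      # odd length: integer delay
  b <- signal::fir1(taps - 1L, c(lo, hi) / (fs / 2), type = "pass")
  gd <- (taps - 1L) %/% 2L
  x <- audioSamples(audio)
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y <- y[(gd + 1L):(gd + length(x))]
  audioRecording(y, fs, audio@startTime)
}

# RMS envelope and rolling-median carrier level of a band-limited signal.
.envelopeAndLevel <- function(x, fs, config) {
  k <- max(8L, round(config@envelopeSmooth * fs))
  env <- sqrt(pmax(.movingMean(x^2, k), 0))
  # carrier level: rolling median of the envelope on a ~5 ms grid
  d <- max(1L, round(fs / 200))
  idx <- seq(1L, length(x), by = d)
  envD <- env[idx]
  span <- round(config@carrierSpan * 200)
  if (span %% 2L == 0L) span <- span + 1L
  span <- min(span, length(envD) - (1 - length(envD) %% 2L))
  level <- if (span >= 3L && length(envD) >= span)
    runmed(envD, span, endrule = "median") else
      rep(median(envD), length(envD))
  levelFull <- approx(idx, level, xout = seq_along(x), rule = 2)$y
  list(envelope = env, level = levelFull)
}

#' Detect heartbeats as carrier interruptions
#'
#' Computes the RMS amplitude envelope of the band-limited recording
#' and scores a beat for every contiguous excursion of the envelope
#' below `envelopeThreshold` times the local (rolling-median) carrier
#' amplitude, provided the excursion lasts at least `minEventDuration`
#' and falls at least `refractory` seconds after the previous beat.
#' Events are tallied over non-overlapping `windowLen`-sample windows,
#' giving `sampleRate / windowLen` counting windows per second (96 per
#' second at 48 kHz with the default 500-sample window). A recording
#' whose median envelope sits below `silenceFloor` is returned with
#' all-zero counts and a `"silent"` flag rather than an error.
#'
#' @param filtered a band-limited [AudioRecording] (see
#'   [bandpassFilter()]).
#' @param config a [detectionConfig()].
#' @return A [BeatEvents] object.
#' @export
detectBeats <- function(filtered, config = detectionConfig()) {
  stopifnot(is(filtered, "AudioRecording"))
  fs <- sampleRate(filtered)
  x <- audioSamples(filtered)
  n <- length(x)
  wl <- as.integer(config@windowLen)
  nW <- n %/% wl
  windowTimes <- filtered@startTime + (seq_len(nW) - 1L) * wl / fs

  ee <- .envelopeAndLevel(x, fs, config)
  if (median(ee$envelope) < config@silenceFloor) {
    return(new("BeatEvents", eventTimes = numeric(0),
               windowCounts = rep(0L, nW), windowTimes = windowTimes,
               windowLen = wl, sampleRate = fs, flags = "silent"))
  }
  below <- ee$envelope < config@envelopeThreshold * ee$level
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= config@minEventDuration * fs)
  eventSamp <- starts[runs]
  eventTimes <- filtered@startTime + (eventSamp - 1L) / fs
  if (length(eventTimes) > 1L && config@refractory > 0) {
    keep <- logical(length(eventTimes))
    keep[1L] <- TRUE
    last <- eventTimes[1L]
    for (i in 2L:length(eventTimes)) {
      if (eventTimes[i] - last >= config@refractory) {
        keep[i] <- TRUE
        last <- eventTimes[i]
      }
    }
    eventTimes <- eventTimes[keep]
    eventSamp <- eventSamp[keep]
  }
  winIdx <- (eventSamp - 1L) %/% wl + 1L
  inWin <- winIdx >= 1L & winIdx <= nW
  counts <- tabulate(winIdx[inWin], nbins = nW)
  new("BeatEvents", eventTimes = eventTimes,
      windowCounts = as.integer(counts), windowTimes = windowTimes,
      windowLen = wl, sampleRate = fs, flags = character(0))
}

#' Convert beat events to a heart-rate series
#'
#' Aggregates events into bins of `aggregation` seconds:
#' bpm = 60 x events / bin duration. Only bins fully covered by the
#' analysed windows are emitted; there is no coverage beyond the last
#' complete window, so partial trailing bins are dropped rather than
#' reported as zero.
#'
#' @param events a [BeatEvents] from [detectBeats()].
#' @param aggregation bin length in seconds; must be at least one
#'   counting-window duration.
#' @return A [HeartRateSeries] with one value per bin (timestamped at
#'   the bin end).
#' @export
countsToRate <- function(events, aggregation = 1) {
  stopifnot(is(events, "BeatEvents"))
  windowDur <- events@windowLen / events@sampleRate
  if (aggregation < windowDur)
    stop("aggregation must be at least one window duration (",
         signif(windowDur, 3), " s)")
  if (!length(events@windowTimes))
    return(heartRateSeries(numeric(0), numeric(0), character(0)))
  t0 <- events@windowTimes[1L]
  coverage <- length(events@windowTimes) * windowDur
  nBins <- floor(coverage / aggregation + 1e-9)
  if (nBins < 1L)
    stop("recording shorter than one aggregation bin")
  edges <- t0 + (0:nBins) * aggregation
  counts <- tabulate(
    findInterval(events@eventTimes, edges, rightmost.closed = TRUE),
    nbins = nBins)
  heartRateSeries(time = edges[-1L], bpm = 60 * counts / aggregation,
                  quality = "raw")
}

#' Kernel-density quantile filter for heart-rate series
#'
#' Estimates the density of the bpm values (Gaussian KDE, Silverman's
#' bandwidth unless overridden) and flags values lying outside the
#' retained region as `"filtered-out"`: either outside the
#' `kdeQuantile` highest-density region (`kdeMethod = "hdr"`, default)
#' or outside the central `kdeQuantile` probability interval
#' (`"interval"`). Surviving values are unchanged, so the filter can
#' never widen the value range. Heart rate is strongly autocorrelated,
#' so isolated static-induced outliers sit in low-density regions and
#' are removed while sustained physiological rates survive.
#'
#' @param series a [HeartRateSeries].
#' @param config a [detectionConfig()] (uses `kdeQuantile`,
#'   `kdeBandwidth`, `kdeMethod`).
#' @return The series with updated quality flags.
#' @export
kdeQuantileFilter <- function(series, config = detectionConfig()) {
  stopifnot(is(series, "HeartRateSeries"))
  usable <- which(series@quality == "raw" & is.finite(series@bpm))
  if (length(usable) < 10L)
    stop("need at least 10 finite raw values for the KDE filter")
  vals <- series@bpm[usable]
  bw <- if (is.numeric(config@kdeBandwidth)) config@kdeBandwidth else
    bw.nrd0(vals)
  if (!is.finite(bw) || bw <= 0) return(series)   # degenerate: constant
  d <- density(vals, bw = bw, n = 1024)
  dx <- d$x[2L] - d$x[1L]
  fi <- approx(d$x, d$y, xout = vals, rule = 2)$y
  if (config@kdeMethod == "hdr") {
    ord <- order(d$y, decreasing = TRUE)
    cum <- cumsum(d$y[ord]) * dx
    cutoff <- d$y[ord][which(cum >= config@kdeQuantile)[1L]]
    drop <- fi < cutoff
  } else {
    Fx <- cumsum(d$y) * dx
    Fx <- Fx / Fx[length(Fx)]
    a <- (1 - config@kdeQuantile) / 2
    loX <- d$x[which(Fx >= a)[1L]]
    hiX <- d$x[which(Fx >= 1 - a)[1L]]
    drop <- vals < loX | vals > hiX
  }
  if (all(drop))
    stop("all values rejected by the KDE filter: pathological recording")
  q <- series@quality
  q[usable[drop]] <- "filtered-out"
  new("HeartRateSeries", time = series@time, bpm = series@bpm, quality = q)
}

#' Trailing-window smoothing of a heart-rate series
#'
#' The value at each requested timestamp is the mean of the usable raw
#' bpm values in the preceding `(t - window, t]` interval (a causal,
#' trailing window — the smoothing used to match a heart rate to each
#' body-temperature sample). Timestamps whose window contains no data
#' get `NA`.
#'
#' @param series a [HeartRateSeries]; `"filtered-out"` values are
#'   ignored.
#' @param window window length in seconds (default 60).
#' @param at timestamps to evaluate at (default: the series' own times).
#' @return A [HeartRateSeries] with quality `"interpolated"`.
#' @export
smoothRate <- function(series, window = 60, at = NULL) {
  stopifnot(is(series, "HeartRateSeries"))
  if (window <= 0) stop("window must be positive")
  if (is.null(at)) at <- series@time
  ok <- series@quality != "filtered-out" & is.finite(series@bpm)
  tt <- series@time[ok]
  vv <- series@bpm[ok]
  out <- vapply(at, function(t) {
    sel <- tt > t - window & tt <= t
    if (any(sel)) mean(vv[sel]) else NA_real_
  }, numeric(1))
  heartRateSeries(time = at, bpm = out, quality = "interpolated")
}

#' Emulate hand-scoring of heart rate at one-minute cadence
#'
#' Reproduces the manual scoring scheme used when interference defeats
#' full automated scoring: count all heartbeats within the first 10 s
#' of every minute and multiply by six. Only the sampling scheme is
#' emulated; counting within the excerpt reuses the automated detector.
#' A minute whose first 10 s are silent scores 0 bpm even if the
#' remainder is active — the scheme's documented bias.
#'
#' @param audio an unfiltered [AudioRecording] of at least one minute.
#' @param config a [detectionConfig()].
#' @param carrier carrier frequency in Hz; estimated from the first
#'   excerpt when `NULL`.
#' @return A [HeartRateSeries] with one value per complete minute,
#'   timestamped at the minute start.
#' @export
manualScoreEmulation <- function(audio, config = detectionConfig(),
                                 carrier = NULL) {
  stopifnot(is(audio, "AudioRecording"))
  fs <- sampleRate(audio)
  nMin <- floor(duration(audio) / 60)
  if (nMin < 1L) stop("recording must be at least one minute long")
  x <- audioSamples(audio)
  bpm <- numeric(nMin)
  for (m in seq_len(nMin)) {
    i0 <- round((m - 1) * 60 * fs) + 1L
    excerpt <- audioRecording(x[i0:(i0 + round(10 * fs) - 1L)], fs)
    cur <- carrier
    if (is.null(cur)) {
      cur <- tryCatch(estimateCarrierFrequency(excerpt, config),
                      error = function(e) NA_real_)
      if (!is.na(cur)) carrier <- cur        # cache once found
    }
    if (is.na(cur)) {
      bpm[m] <- 0
      next
    }
    ev <- detectBeats(bandpassFilter(excerpt, cur, config), config)
    bpm[m] <- 6 * length(beatTimes(ev))
  }
  heartRateSeries(time = audio@startTime + (seq_len(nMin) - 1) * 60,
                  bpm = bpm, quality = "raw")
}
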