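# Carrier estimation, band-pass filtering, beat detection, rate
# conversion, and the hand-scoring emulation.

test_that("carrier frequency is recovered to within one bin", {
  fs <- 48000
  tone <- audioRecording(sin(2 * pi * 2000 * (0:(fs - 1)) / fs), fs)
  expect_lt(abs(estimateCarrierFrequency(tone) - 2000), fs / 65536 + 1)

  out <- cleanAudio(300, seconds = 4, noiseSd = 0.1, seed = 5)
  expect_lt(abs(estimateCarrierFrequency(out$audio) - 1500), 1.5)

  set.seed(6)
  noise <- audioRecording(rnorm(fs), fs)
  expect_error(estimateCarrierFrequency(noise), "no carrier")
})

test_that("band-pass preserves the pass band and rejects out-of-band energy", {
  fs <- 48000
  t <- (0:(5 * fs - 1)) / fs
  inBand <- audioRecording(sin(2 * pi * 1500 * t), fs)
  outBand <- audioRecording(sin(2 * pi * 3000 * t), fs)
  gIn <- sd(audioSamples(bandpassFilter(inBand, 1500))) /
    sd(audioSamples(inBand))
  gOut <- sd(audioSamples(bandpassFilter(outBand, 1500))) /
    sd(audioSamples(outBand))
  expect_lt(abs(20 * log10(gIn)), 1)       # within 1 dB of unity
  expect_lt(20 * log10(gOut), -20)         # >= 20 dB attenuation at 2x

  # idempotence within pass-band ripple
  once <- bandpassFilter(inBand, 1500)
  twice <- bandpassFilter(once, 1500)
  mid <- (fs):(4 * fs)                     # ignore edge transients
  expect_equal(sd(audioSamples(twice)[mid]), sd(audioSamples(once)[mid]),
               tolerance = 0.02)

  expect_error(bandpassFilter(inBand, 23950), "Nyquist")
})

test_that("beats are counted at the configured window resolution", {
  out <- cleanAudio(120, seconds = 10)
  ev <- detectBeats(bandpassFilter(out$audio, 1500))
  # 48 kHz / 500-sample windows = 96 windows per second
  expect_equal(ev@sampleRate / ev@windowLen, 96)
  expect_length(windowCounts(ev), 960)
  expect_lte(abs(length(beatTimes(ev)) - 20), 1)
  # window counts tally every detected event
  expect_equal(sum(windowCounts(ev)), length(beatTimes(ev)))
})

test_that("a beat-free or silent recording yields zero events", {
  quiet <- synthesizeTransmitterAudio(
    signalSpec(sampleRate = 48000, noiseSd = 0), constantRate(0, 3))
  ev <- detectBeats(bandpassFilter(quiet$audio, 1500))
  expect_length(beatTimes(ev), 0)

  silent <- audioRecording(rep(0, 48000), 48000)
  ev2 <- detectBeats(silent)
  expect_true("silent" %in% ev2@flags)
  expect_true(all(windowCounts(ev2) == 0))
})

test_that("counts convert to bpm by events per bin duration", {
  out <- cleanAudio(60, seconds = 60, fs = 22050)
  ev <- detectBeats(bandpassFilter(out$audio, 1500))
  hr <- countsToRate(ev, aggregation = 60)
  expect_equal(hr@bpm[1L], 60, tolerance = 0.02)

  # 10 events in a 6-s bin -> 100 bpm
  out2 <- cleanAudio(100, seconds = 6.2, fs = 22050)
  ev2 <- detectBeats(bandpassFilter(out2$audio, 1500))
  hr2 <- countsToRate(ev2, aggregation = 6)
  expect_equal(hr2@bpm[1L], 100, tolerance = 0.02)

  expect_error(countsToRate(ev, aggregation = 0.005), "window duration")
})

test_that("hand-scoring emulation scales first-10-s counts by six", {
  out <- cleanAudio(300, seconds = 120, fs = 22050, noiseSd = 0.05,
                    seed = 8)
  hs <- manualScoreEmulation(out$audio)
  expect_length(hs@bpm, 2)
  expect_true(all(abs(hs@bpm - 300) <= 6))

  # silence in the first 10 s of a minute biases that minute to zero
  x <- audioSamples(out$audio)
  x[seq_len(10 * 22050)] <- 0
  biased <- manualScoreEmulation(audioRecording(x, 22050))
  expect_equal(biased@bpm[1L], 0)
  expect_true(abs(biased@bpm[2L] - 300) <= 6)
})
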