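# Kernel-density outlier rejection and trailing-window smoothing.

test_that("KDE filter removes isolated artifacts and keeps the cluster", {
  set.seed(2)
  v <- c(rnorm(95, 70, 1), rep(2000, 5))
  s <- heartRateSeries(seq_along(v), v)
  for (m in c("hdr", "interval")) {
    f <- kdeQuantileFilter(s, detectionConfig(kdeBandwidth = 5,
                                              kdeMethod = m))
    flagged <- which(f@quality == "filtered-out")
    expect_identical(flagged, 96:100)
    # surviving values are unchanged
    expect_identical(f@bpm, s@bpm)
  }
})

test_that("KDE filter leaves a constant series unchanged", {
  s <- heartRateSeries(1:20, rep(80, 20))
  f <- kdeQuantileFilter(s)
  expect_true(all(f@quality == "raw"))
})

test_that("removing flagged values cannot widen the spread", {
  set.seed(9)
  for (rep in 1:5) {
    v <- c(rnorm(80, 150, 30), runif(10, 500, 1500))
    s <- heartRateSeries(seq_along(v), v)
    # the value range can never widen under either reading
    for (m in c("hdr", "interval")) {
      f <- kdeQuantileFilter(s, detectionConfig(kdeMethod = m))
      kept <- f@bpm[f@quality == "raw"]
      expect_lte(diff(range(kept)), diff(range(v)))
    }
    # the central-interval reading keeps a contiguous value band, so
    # the interquartile range cannot widen either
    fi <- kdeQuantileFilter(s, detectionConfig(kdeMethod = "interval"))
    kept <- fi@bpm[fi@quality == "raw"]
    expect_lte(IQR(kept), IQR(v) + 1e-9)
  }
})

test_that("KDE filter refuses tiny inputs", {
  expect_error(kdeQuantileFilter(heartRateSeries(1:5, rep(70, 5))),
               "at least 10")
})

test_that("trailing smooth equals the brute-force window mean", {
  # constant input -> constant output
  s <- heartRateSeries(1:100, rep(120, 100))
  expect_true(all(smoothRate(s, 60)@bpm == 120))

  # linear ramp 0 -> 120 over 60 s, evaluated at t = 60: mean = 60
  tt <- seq(0.5, 59.5, by = 1)
  ramp <- heartRateSeries(tt, 2 * tt)
  expect_equal(smoothRate(ramp, 60, at = 60)@bpm, 60)

  # random series against an independently coded oracle
  set.seed(4)
  tt <- sort(runif(200, 0, 500))
  vv <- runif(200, 50, 900)
  s2 <- heartRateSeries(tt, vv)
  at <- seq(30, 480, by = 37)
  got <- smoothRate(s2, 60, at = at)@bpm
  oracle <- sapply(at, function(t) {
    w <- vv[tt > t - 60 & tt <= t]
    if (length(w)) sum(w) / length(w) else NA_real_
  })
  expect_equal(got, oracle)

  # empty window -> missing, not zero
  expect_true(is.na(smoothRate(s2, 60, at = 1000)@bpm))
})
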