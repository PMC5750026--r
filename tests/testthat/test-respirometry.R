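# Gas-exchange equations against hand-computed values, baseline
# correction round trips, alignment, and minimum-state extraction.

test_that("CO2 equation variants reproduce hand-computed values", {
  expect_equal(computeVCO2(0.001, 0, 300, 0.8), 0.3 / (1 - 0.001 * 0.8))
  expect_equal(computeVCO2(0.001, 0, 300, 0.8), 0.3002402, tolerance = 1e-6)
  expect_equal(computeVCO2(0.001, 0, 300, 0.8, variant = "textbook"),
               0.3 / (1 - 0.001 * (1 - 1 / 0.8)))
  expect_equal(computeVCO2(0.001, 0, 300, 0.8, variant = "textbook"),
               0.2999250, tolerance = 1e-6)
  # equal fractions -> zero, either variant
  expect_equal(computeVCO2(0.002, 0.002, 300, 0.8), 0)
  expect_equal(computeVCO2(0.002, 0.002, 300, 0.8, variant = "textbook"), 0)
  expect_error(computeVCO2(0.001, 0, 300, 1.2), "rer")
})

test_that("variant divergence stays within its analytic envelope at low CO2", {
  # relative divergence is FeCO2 * (1/RER - RER) / (1 + FeCO2 (1 - 1/RER)),
  # i.e. ~0.45 FeCO2/RER: 0.105 percent at FeCO2 = 0.001 and 0.53 percent
  # at the 0.005 upper end of the small-animal range
  fe <- seq(1e-4, 0.005, length.out = 30)
  a <- computeVCO2(fe, 0, 300, 0.8)
  b <- computeVCO2(fe, 0, 300, 0.8, variant = "textbook")
  expect_true(all(abs(a - b) / a < 0.0053))
  expect_lt(abs(a[1L] - b[1L]) / a[1L], 0.002)
  expect_true(all(abs(a - b) / a <= 0.0053 * fe / 0.005 + 1e-9))
})

test_that("O2 equation and power conversion match independent arithmetic", {
  expect_equal(computeVO2(0.2090, 0.2095, 300), 300 * 5e-4 / 0.7905)
  expect_equal(computeVO2(0.2090, 0.2095, 300), 0.18975, tolerance = 1e-4)
  expect_equal(computeVO2(0.21, 0.21, 300), 0)
  expect_error(computeVO2(0.9, 1, 300), "fio2")

  p <- vco2ToPower(0.30024, massG = 10.5)
  expect_equal(p$kj_h, 0.45036)
  expect_equal(p$w_g, 0.30024 * 25 / 60 / 10.5)
  expect_equal(p$w_g, 0.0119143, tolerance = 1e-5)
  # unit identity kJ/h / 3.6 / mass == W/g
  v <- runif(20, 0, 2)
  p2 <- vco2ToPower(v, massG = 8)
  expect_equal(p2$kj_h / 3.6 / 8, p2$w_g)
  expect_equal(vco2ToPower(0)$kj_h, 0)
})

test_that("baseline correction removes linear analyzer drift exactly", {
  ch <- chamberSpec(driftSlope = 5e-4)
  tr <- simulateRespirometryTrace(ch, 0, rer = 0.8, duration = 7200)
  cor <- baselineCorrect(tr)
  animal <- !cor@baselineMask
  expect_lt(max(abs(cor@feco2[animal] - cor@fico2[animal])), 1e-6)
  expect_lt(max(abs(cor@feo2[animal] - cor@fio2[animal])), 1e-6)
})

test_that("single or missing baselines fall back as documented", {
  ch <- chamberSpec(baselineSchedule = list(c(0, 300)))
  tr <- simulateRespirometryTrace(ch, 0.3, rer = 0.8, duration = 3600)
  expect_message(baselineCorrect(tr), "single baseline")

  tr2 <- simulateRespirometryTrace(chamberSpec(), 0.3, rer = 0.8,
                                   duration = 3600)
  tr2@baselineMask <- rep(FALSE, length(tr2@time))
  expect_error(baselineCorrect(tr2), "incurrent")
  cor2 <- baselineCorrect(tr2, incurrent = c(co2 = 4e-4, o2 = 0.2095))
  expect_true(cor2@corrected)
})

test_that("the exchange ratio is recovered from a synthetic trace", {
  tr <- simulateRespirometryTrace(chamberSpec(), 0.45, rer = 0.8,
                                  duration = 7200)
  met <- computeMetabolicSeries(baselineCorrect(tr), rer = 0.8)
  expect_equal(computeRER(met@vco2, met@vo2), 0.8, tolerance = 1e-3)
  # identical series -> ratio one; constant series -> methods agree
  expect_equal(computeRER(rep(0.3, 5), rep(0.3, 5)), 1)
  expect_equal(computeRER(rep(0.24, 9), rep(0.3, 9), "mean-of-ratios"),
               computeRER(rep(0.24, 9), rep(0.3, 9), "ratio-of-means"))
  expect_error(computeRER(c(0.1, 0.2), c(0, -1)), "positive")
})

test_that("gas samples align with five Tb/fH pairs and brute-force means", {
  tb <- data.frame(time = seq(60, 3600, by = 60), tb = 30 + sin(1:60 / 9))
  hrRaw <- heartRateSeries(seq(1, 3600, by = 2),
                           100 + 20 * sin(seq(1, 3600, by = 2) / 500))
  metTime <- seq(300, 3600, by = 300)
  met <- new("MetabolicSeries", time = metTime,
             vco2 = rep(0.3, 12), vo2 = rep(0.375, 12),
             mrKjH = rep(0.45, 12), mrWg = rep(0.0042, 12), massG = 10.5)
  al <- alignMeasures(tb, hrRaw, met)
  expect_true(all(al$perSample$n_pairs == 5))
  expect_equal(nrow(al$perTb), 60)
  # per-sample means equal brute-force window means
  i <- 4
  sel <- tb$time > metTime[i] - 300 & tb$time <= metTime[i]
  expect_equal(al$perSample$tb[i], mean(tb$tb[sel]))
  sm <- smoothRate(hrRaw, 60, at = tb$time)
  expect_equal(al$perSample$fh[i], mean(sm@bpm[sel]))
  # constant inputs come back as the constants
  expect_true(all(al$perSample$mr_kj_h == 0.45))
})

test_that("minimum states follow the type-7 quantile convention", {
  d <- data.frame(individual = "a", mr_kj_h = 1:100,
                  fh = 1:100, tb = 1:100)
  ms <- minimumStates(d, quantile = 0.10)
  expect_identical(ms$records$mr_kj_h, 1:10)
  expect_equal(ms$summary$threshold, quantile(1:100, 0.1, names = FALSE))
  # all-equal MR: every record selected
  d2 <- data.frame(individual = "a", mr_kj_h = rep(2, 20))
  expect_equal(nrow(minimumStates(d2)$records), 20)
  # q = 1 reduces to the whole-data mean
  expect_equal(minimumStates(d, quantile = 1)$summary$mean_mr, mean(1:100))
  # invariant to record order
  shuffled <- d[sample(nrow(d)), ]
  ms2 <- minimumStates(shuffled, quantile = 0.10)
  expect_equal(sort(ms2$records$mr_kj_h), sort(ms$records$mr_kj_h))
  expect_equal(ms2$summary$mean_mr, ms$summary$mean_mr)
  # too few records: skipped with a warning
  d3 <- rbind(d, data.frame(individual = "b", mr_kj_h = 1:3,
                            fh = 1:3, tb = 1:3))
  expect_warning(minimumStates(d3), "skipped")
})

test_that("steady-state mask flags low rolling variation", {
  expect_true(all(steadyStateMask(rep(0.4, 30))))
  expect_false(any(steadyStateMask(rep(c(0.1, 0.9), 15))))
  expect_error(steadyStateMask(rep(0.4, 30), window = 2), "3 samples")
})

test_that("forward simulation round-trips through the analysis path", {
  mrT <- data.frame(time = seq(0, 7200, by = 60),
                    mr_kj_h = 0.3 + 0.15 * sin(seq(0, 7200, by = 60) / 900))
  # noise-free: within 1 percent
  tr <- simulateRespirometryTrace(chamberSpec(), mrT, rer = 0.8,
                                  duration = 7200)
  met <- computeMetabolicSeries(baselineCorrect(tr), rer = 0.8,
                                sampleSeconds = NULL)
  truth <- approx(mrT$time, mrT$mr_kj_h, xout = met@time, rule = 2)$y
  expect_lt(max(abs(met@mrKjH - truth) / truth), 0.01)
  # noise at 2 percent of the signal differential: recover within 5 percent
  diffScale <- 0.3 * 1000 / 25 / 60 / 300          # typical FeCO2 - FiCO2
  trN <- simulateRespirometryTrace(
    chamberSpec(noiseSd = 0.02 * diffScale), mrT, rer = 0.8,
    duration = 7200, seed = 21)
  metN <- computeMetabolicSeries(baselineCorrect(trN), rer = 0.8,
                                 sampleSeconds = NULL)
  truthN <- approx(mrT$time, mrT$mr_kj_h, xout = metN@time, rule = 2)$y
  expect_lt(mean(abs(metN@mrKjH - truthN) / truthN), 0.05)
})
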