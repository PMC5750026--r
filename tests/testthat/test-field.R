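# Stream synchronization, low-state classification, hourly summaries,
# field regressions and expenditure integration.

test_that("streams synchronize on the Tb time base without fabricating rows", {
  sim <- simulateFieldDataset(days = 1, cadenceTb = "10min",
                              cadenceFh = "10min", noiseScale = 0,
                              torporSchedule = list(),
                              returnSpike = FALSE, seed = 1)
  rec <- syncStreams(sim$hr, sim$tb, sim$ta)
  expect_equal(nrow(rec), nrow(sim$tb))         # one record per Tb sample
  expect_true(all(diff(as.numeric(rec$timestamp)) >= 600))
  # matched Ta equals the table value at every 15-min gridpoint
  onGrid <- rec[rec$timestamp %in% sim$ta$timestamp, ]
  expect_equal(onGrid$ta,
               sim$ta$ta[match(onGrid$timestamp, sim$ta$timestamp)])
  expect_equal(rec$tdiff, rec$tb - rec$ta)
  # constant heart rate passes through the trailing smooth unchanged
  expect_true(all(rec$fh == 147))

  taShift <- sim$ta
  taShift$timestamp <- taShift$timestamp + 10 * 86400
  hrShift <- sim$hr
  hrShift$timestamp <- hrShift$timestamp + 10 * 86400
  expect_error(syncStreams(hrShift, sim$tb, sim$ta), "overlap")
})

test_that("low-state classification matches a brute-force sort", {
  ts <- as.POSIXct("2016-03-01", tz = "UTC") + seq(0, by = 600,
                                                   length.out = 100)
  rec <- data.frame(timestamp = ts, individual = "b1",
                    fh = seq(10, 1000, by = 10), tb = 30)
  low <- classifyLowState(rec, quantile = 0.10)
  expect_equal(low$threshold,
               quantile(seq(10, 1000, 10), 0.1, names = FALSE))
  expect_identical(which(low$records$low_state), 1:10)
  # all-equal values: everything is at the quantile, all flagged
  rec2 <- rec
  rec2$fh <- 100
  expect_true(all(classifyLowState(rec2)$records$low_state))
  expect_error(classifyLowState(rec[1:5, ]), "at least 10")
})

test_that("low-state detection is sensitive and specific at default noise", {
  sim <- simulateFieldDataset(nIndividuals = 2, seed = 5)
  rec <- syncStreams(sim$hr, sim$tb, sim$ta)
  low <- classifyLowState(rec)
  m <- merge(low$records, sim$truth, by = c("timestamp", "individual"))
  expect_gte(mean(m$low_state[m$torpid]), 0.9)       # sensitivity
  expect_gte(mean(!m$low_state[!m$torpid]), 0.9)     # specificity
})

test_that("hourly summaries equal a brute-force group-by", {
  set.seed(12)
  ts <- as.POSIXct("2016-03-01", tz = "UTC") +
    sort(sample(0:(2 * 86400), 1000))
  rec <- data.frame(timestamp = ts, individual = "b1",
                    fh = runif(1000, 50, 900), tb = runif(1000, 25, 38))
  hs <- hourlySummary(rec)
  hour <- as.numeric(format(ts, "%H"))
  for (h in c(0, 7, 15, 23)) {
    sel <- hour == h
    expect_equal(hs$mean_fh[hs$hour == h], mean(rec$fh[sel]))
    expect_equal(hs$sd_tb[hs$hour == h], sd(rec$tb[sel]))
    expect_equal(hs$n_fh[hs$hour == h], sum(sel))
  }
  # a single record populates exactly its own hour; others stay NA
  one <- rec[format(rec$timestamp, "%H") == "13", ][1, ]
  hs1 <- hourlySummary(one)
  expect_equal(hs1$n_fh[hs1$hour == 13], 1)
  expect_true(all(is.na(hs1$mean_fh[hs1$hour != 13])))
  expect_equal(sum(hs1$n_fh), 1)
})

test_that("scotophase annotation wraps midnight, closed at dusk", {
  ts <- function(s) as.POSIXct(paste("2016-03-01", s), tz = "UTC")
  expect_true(scotophaseAnnotation(ts("00:00:00")))
  expect_false(scotophaseAnnotation(ts("12:00:00")))
  expect_true(scotophaseAnnotation(ts("18:15:00")))   # closed at dusk
  expect_false(scotophaseAnnotation(ts("06:15:00")))  # open at dawn
  expect_error(scotophaseAnnotation(ts("00:00:00"), "10:00", "10:00"),
               "differ")
})

test_that("field regressions recover the generating slopes", {
  slTa <- slTb <- numeric(20)
  for (i in 1:20) {
    rec <- fieldRegressionData(seed = 900 + i)
    fr <- fieldRegressions(rec)
    slTa[i] <- fr$table$slope[fr$table$model == "tb ~ ta"]
    slTb[i] <- fr$table$slope[fr$table$model == "fh ~ tb"]
  }
  expect_lt(abs(mean(slTa) / 0.481 - 1), 0.15)
  expect_lt(abs(mean(slTb) / 14.985 - 1), 0.10)
  # single-fit table sanity: chi2 positive, p tiny, r2m <= r2c
  fr <- fieldRegressions(fieldRegressionData(seed = 1))
  expect_true(all(fr$table$chi2 > 0))
  expect_true(all(fr$table$p < 0.001))
  expect_true(all(fr$table$r2m <= fr$table$r2c + 1e-12))
})

test_that("expenditure totals integrate coverage without imputation", {
  ts <- as.POSIXct("2016-03-01", tz = "UTC") + seq(0, 86340, by = 60)
  rec <- data.frame(timestamp = ts, individual = "b1", fh = 147)
  cc <- calibrationCoefficients(unit = "kJ/h")
  pe <- predictFieldExpenditure(rec, cc)
  expect_equal(pe$daily$total_kj, 24 * (0.00106 * 147 + 0.0527),
               tolerance = 1e-9)
  expect_true(pe$daily$reliable)
  # f_H = 0 predicts the intercept
  expect_equal(as.numeric(predictExpenditure(0, cc)), 0.0527)
  # a half-day gap halves the total (no imputation)
  half <- rec[1:720, ]
  peHalf <- predictFieldExpenditure(half, cc)
  expect_equal(peHalf$daily$total_kj, pe$daily$total_kj / 2,
               tolerance = 1e-6)
  # a day with > 50 percent gap is flagged unreliable
  sparse <- rec[1:300, ]
  expect_false(predictFieldExpenditure(sparse, cc)$daily$reliable)
  # kJ/d calibrations are integrated on the day scale
  ccD <- calibrationCoefficients(unit = "kJ/d")
  peD <- predictFieldExpenditure(rec, ccD)
  expect_equal(peD$daily$total_kj, pe$daily$total_kj / 24,
               tolerance = 1e-9)
})
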