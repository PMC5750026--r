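# Generator contracts: calibration-table structure and variances,
# respirometry forward-model identities, field-dataset ground truth.

test_that("calibration generator honours the design size and the exact line", {
  d <- simulateCalibrationDataset(
    mixedModelSpec(nIndividuals = 2, nObsPerIndividual = 2,
                   sigmaIndividual = 0, sigmaResidual = 0, seed = 1))
  expect_equal(nrow(d), 4)
  expect_equal(nlevels(d$individual), 2)
  expect_equal(d$mr, 0.0527 + 0.00106 * d$fh)
  expect_identical(attr(d, "unit"), "kJ/d")
})

test_that("per-individual mean variance approaches sigma_u^2 + sigma_e^2 / n", {
  spec <- mixedModelSpec(sigmaIndividual = 0.05, sigmaResidual = 0.108,
                         nIndividuals = 200, nObsPerIndividual = 1000,
                         seed = 77)
  d <- simulateCalibrationDataset(spec)
  centered <- d$mr - (0.0527 + 0.00106 * d$fh)
  perInd <- tapply(centered, d$individual, mean)
  expected <- 0.05^2 + 0.108^2 / 1000
  expect_equal(var(as.numeric(perInd)), expected, tolerance = 0.15)
})

test_that("respirometry forward model obeys its boundary identities", {
  # zero metabolism, no drift or noise: excurrent equals incurrent
  tr <- simulateRespirometryTrace(chamberSpec(), 0, rer = 0.8,
                                  duration = 1800)
  expect_true(all(tr@feco2 == tr@fico2))
  expect_true(all(tr@feo2 == tr@fio2))
  expect_error(simulateRespirometryTrace(chamberSpec(), -0.1, rer = 0.8,
                                         duration = 600), "non-negative")
  # known constant MR inverts through the printed equation within 1 pct
  tr2 <- simulateRespirometryTrace(chamberSpec(), 0.45, rer = 0.8,
                                   duration = 3600)
  keep <- !tr2@baselineMask
  v <- computeVCO2(tr2@feco2[keep], tr2@fico2[keep], 300, 0.8)
  expect_equal(mean(v), 0.30, tolerance = 0.01)
})

test_that("field generator keeps active records above the floor and hits the Ta means", {
  sim <- simulateFieldDataset(torporSchedule = list(), noiseScale = 0,
                              seed = 1)
  expect_gte(min(sim$hr$fh), 100)
  # diel ambient cycle reproduces the photoperiod means
  simT <- simulateFieldDataset(days = 4, torporSchedule = list(), seed = 2)
  sc <- scotophaseAnnotation(simT$ta$timestamp, "18:15", "06:15")
  expect_equal(mean(simT$ta$ta[!sc]), 25.87, tolerance = 0.2)
  expect_equal(mean(simT$ta$ta[sc]), 23.74, tolerance = 0.2)
})

test_that("a scheduled torpor bout is flagged in exactly its hours", {
  sim <- simulateFieldDataset(days = 1, torporSchedule = list(c(8, 12)),
                              noiseScale = 0, returnSpike = FALSE,
                              seed = 3)
  rec <- syncStreams(sim$hr, sim$tb, sim$ta)
  low <- classifyLowState(rec)
  expect_identical(low$hours, c(8, 9, 10, 11))
  # noise-free: flagged records are exactly the scheduled ones
  m <- merge(low$records, sim$truth, by = c("timestamp", "individual"))
  expect_true(all(m$low_state == m$torpid))
})

test_that("field generation is reproducible under a seed", {
  a <- simulateFieldDataset(seed = 11)
  b <- simulateFieldDataset(seed = 11)
  expect_identical(a$hr, b$hr)
  expect_identical(a$tb, b$tb)
  expect_identical(a$ta, b$ta)
})
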