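# Field-telemetry generator: in-roost heart-rate and body-temperature
# streams for one or more individuals over a diel ambient-temperature
# cycle, with scheduled torpor bouts, early-scotophase foraging gaps
# and optional post-return tachycardia spikes.

.parseClock <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
  p[1L] + p[2L] / 60
}

# Diel sinusoid with prescribed photophase and scotophase means.
# Ta(h) = M + A cos(2 pi (h - peakHour) / 24); M and A are solved so the
# mean over daytime (dawn..dusk) and nighttime hours hit the targets.
.dielTa <- function(hourOfDay, dayMean, nightMean, dawn, dusk,
                    peakHour = 14) {
  base <- function(h) cos(2 * pi * (h - peakHour) / 24)
  grid <- seq(0, 24, by = 0.01)
  isDay <- grid >= dawn & grid < dusk
  cDay <- mean(base(grid[isDay]))
  cNight <- mean(base(grid[!isDay]))
  A <- (dayMean - nightMean) / (cDay - cNight)
  M <- dayMean - A * cDay
  M + A * base(hourOfDay)
}

#' Simulate an in-roost field telemetry dataset
#'
#' Generates the three field input streams with known ground truth:
#' heart rate (1-min "continuous" smoothing product or 10-min spot
#' samples), body temperature (1-min or 10-min), and a 15-min ambient
#' temperature table following a diel cycle with prescribed daytime and
#' nighttime means (defaults 25.87 and 23.74 degrees C, lowland Panama
#' conditions). Scheduled torpor bouts drop the heart rate to a low
#' state (< 90 bpm); outside bouts the rate stays at or above
#' `activeFloor`. Records during the early-scotophase foraging window
#' are removed (missing data), and an optional tachycardia spike decays
#' from ~1000 bpm after the return. Body temperature follows the
#' first-order thermal model driven by a heart-rate-proportional
#' metabolic proxy, so it lags metabolic state.
#'
#' @param days length of the record in days (default 1.5, a 36-h record).
#' @param torporSchedule list of `c(startHour, endHour)` bout intervals
#'   in hours from the start; an empty list yields a plain homeothermic
#'   dataset. The default places ~3.5 h of torpor in a 36-h record.
#' @param taCycle list with `dayMean`, `nightMean`, `noiseSd`.
#' @param cadenceFh,cadenceTb `"1min"` or `"10min"`.
#' @param nIndividuals number of bats (per-individual heart-rate offsets
#'   drawn from N(0, 10 bpm)).
#' @param activeFloor lowest active-state heart rate, bpm.
#' @param activeMean,torporMean state mean heart rates, bpm.
#' @param torporSd torpid-state s.d., bpm.
#' @param noiseScale multiplies all stochastic scatter; 0 gives a
#'   deterministic dataset.
#' @param returnSpike add a post-return tachycardia transient.
#' @param foragingGaps drop records during the foraging window
#'   (40 min after dusk).
#' @param dusk,dawn clock times `"HH:MM"` delimiting scotophase.
#' @param thermal a [thermalSpec()] for the body-temperature dynamics.
#' @param start POSIXct start of the record.
#' @param seed integer seed; `NA` leaves the RNG stream untouched.
#' @return A list with data.frames `hr` (`timestamp`, `individual`,
#'   `fh`), `tb` (`timestamp`, `individual`, `tb`), `ta` (`timestamp`,
#'   `ta`), `truth` (`timestamp`, `individual`, `torpid`), and the
#'   `dusk`/`dawn` settings.
#' @export
simulateFieldDataset <- function(days = 1.5,
                                 torporSchedule = list(c(2, 4), c(25, 26.5)),
                                 taCycle = list(dayMean = 25.87,
                                                nightMean = 23.74,
                                                noiseSd = 0.3),
                                 cadenceFh = c("1min", "10min"),
                                 cadenceTb = c("1min", "10min"),
                                 nIndividuals = 1, activeFloor = 100,
                                 activeMean = 147, torporMean = 70,
                                 torporSd = 6, noiseScale = 1,
                                 returnSpike = TRUE, foragingGaps = TRUE,
                                 dusk = "18:15", dawn = "06:15",
                                 thermal = thermalSpec(),
                                 start = as.POSIXct("2016-03-01 00:00:00",
                                                    tz = "UTC"),
                                 seed = NA_real_) {
  cadenceFh <- match.arg(cadenceFh)
  cadenceTb <- match.arg(cadenceTb)
  if (!is.na(seed)) set.seed(as.integer(seed))
  duskH <- .parseClock(dusk)
  dawnH <- .parseClock(dawn)
  totalMin <- round(days * 24 * 60)
  minGrid <- seq(0, totalMin - 1)                 # minutes from start
  hoursFromStart <- minGrid / 60
  hourOfDay <- (as.numeric(format(start, "%H")) +
                as.numeric(format(start, "%M")) / 60 + hoursFromStart) %% 24

  # ambient temperature at 15-min cadence
  taMin <- seq(0, totalMin - 1, by = 15)
  taHod <- hourOfDay[match(taMin, minGrid)]
  ta <- .dielTa(taHod, taCycle$dayMean, taCycle$nightMean, dawnH, duskH)
  if (noiseScale > 0 && taCycle$noiseSd > 0)
    ta <- ta + rnorm(length(ta), 0, noiseScale * taCycle$noiseSd)
  taTable <- data.frame(timestamp = start + taMin * 60, ta = ta)

  torpid <- rep(FALSE, totalMin)
  for (b in torporSchedule)
    torpid <- torpid | (hoursFromStart >= b[1] & hoursFromStart < b[2])

  # foraging window: 40 min after dusk each day
  foraging <- rep(FALSE, totalMin)
  if (foragingGaps) {
    gapLen <- 40 / 60
    hSince <- (hourOfDay - duskH) %% 24
    foraging <- hSince < gapLen
  }

  hr <- tb <- truth <- vector("list", nIndividuals)
  indOffsets <- if (noiseScale > 0) rnorm(nIndividuals, 0, 10) else
    rep(0, nIndividuals)
  taFull <- approx(as.numeric(taTable$timestamp) - as.numeric(start),
                   taTable$ta, xout = minGrid * 60, rule = 2)$y
  for (i in seq_len(nIndividuals)) {
    id <- sprintf("bat%02d", i)
    activeLevel <- activeMean + indOffsets[i]
    fh <- numeric(totalMin)
    nAct <- sum(!torpid)
    if (noiseScale > 0) {
      shape <- 2 / noiseScale^2
      g <- rgamma(nAct, shape = shape, rate = shape)
    } else g <- rep(1, nAct)
    fh[!torpid] <- activeFloor + (activeLevel - activeFloor) * g
    nTor <- sum(torpid)
    fh[torpid] <- pmax(40, torporMean +
                         noiseScale * rnorm(nTor, 0, torporSd))
    if (returnSpike && foragingGaps) {
      retIdx <- which(diff(c(TRUE, foraging)) == -1L)
      for (r in retIdx) {
        sel <- r:min(r + 19, totalMin)
        decay <- exp(-(sel - r) / 4)
        fh[sel] <- pmax(fh[sel], activeLevel + (1000 - activeLevel) * decay)
      }
    }
    # body temperature from the thermal model, driven by a heart-rate
    # proportional metabolic proxy (calibration-equation scale, kJ/h)
    mrProxy <- 0.00106 * fh + 0.0527
    tbSim <- simulateBodyTemperature(
      thermal,
      mrTraj = data.frame(time = minGrid * 60, mr_kj_h = mrProxy),
      taSeries = data.frame(time = minGrid * 60, ta = taFull),
      internalStep = 5, outputStep = 60)
    tbVals <- tbSim$tb
    if (noiseScale > 0)
      tbVals <- tbVals + rnorm(length(tbVals), 0, noiseScale * 0.2)

    keep <- !foraging
    fhStep <- if (cadenceFh == "1min") 1L else 10L
    tbStep <- if (cadenceTb == "1min") 1L else 10L
    fhIdx <- which(keep & (minGrid %% fhStep == 0L))
    tbIdx <- which(keep & (minGrid %% tbStep == 0L))
    hr[[i]] <- data.frame(timestamp = start + minGrid[fhIdx] * 60,
                          individual = id, fh = fh[fhIdx])
    tb[[i]] <- data.frame(timestamp = start + minGrid[tbIdx] * 60,
                          individual = id, tb = tbVals[tbIdx])
    truth[[i]] <- data.frame(timestamp = start + minGrid * 60,
                             individual = id, torpid = torpid,
                             foraging = foraging)
  }
  list(hr = do.call(rbind, hr), tb = do.call(rbind, tb), ta = taTable,
       truth = do.call(rbind, truth), dusk = dusk, dawn = dawn)
}
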