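# In-roost inference: synchronize heart-rate, body-temperature and
# ambient-temperature streams, summarize by hour and photoperiod,
# classify low-energy-state records, fit the field regressions, and
# predict energy expenditure.

#' Annotate timestamps with the scotophase (dark phase)
#'
#' TRUE for times in the dusk-to-dawn wrap-around interval, closed at
#' dusk and open at dawn. Default times approximate the tropical
#' lowland photoperiod at the study site (Gamboa, Panama).
#'
#' @param timestamps POSIXct vector.
#' @param dusk,dawn clock times `"HH:MM"`; must differ.
#' @return Logical vector.
#' @export
scotophaseAnnotation <- function(timestamps, dusk = "18:15",
                                 dawn = "06:15") {
  duskH <- .parseClock(dusk)
  dawnH <- .parseClock(dawn)
  if (duskH == dawnH) stop("dusk and dawn must differ")
  h <- as.numeric(format(timestamps, "%H")) +
    as.numeric(format(timestamps, "%M")) / 60 +
    as.numeric(format(timestamps, "%S")) / 3600
  if (duskH > dawnH) h >= duskH | h < dawnH else h >= duskH & h < dawnH
}

#' Synchronize heart-rate, body-temperature and ambient streams
#'
#' Builds one record per body-temperature observation: the trailing
#' 60-s mean heart rate of the same individual, and the ambient
#' temperature matched by the configured rule (`"nearest"` 15-min
#' reading by default, linear interpolation optional). Observations
#' without heart-rate data in the window are carried with missing
#' `fh`, never fabricated. Records with `tb < ta` are retained and
#' flagged (`tb_below_ta`), as observed in cool roost microhabitats.
#'
#' @param hr data.frame `timestamp`, `individual`, `fh`.
#' @param tb data.frame `timestamp`, `individual`, `tb`.
#' @param ta data.frame `timestamp`, `ta` (typically 15-min cadence).
#' @param taMethod `"nearest"` or `"interp"`.
#' @param smoothWindow trailing heart-rate window, seconds.
#' @param dusk,dawn scotophase delimiters, `"HH:MM"`.
#' @return A data.frame of field records: `timestamp`, `individual`,
#'   `fh`, `tb`, `ta`, `tdiff`, `scotophase`, `tb_below_ta`.
#' @export
syncStreams <- function(hr, tb, ta, taMethod = c("nearest", "interp"),
                        smoothWindow = 60, dusk = "18:15",
                        dawn = "06:15") {
  taMethod <- match.arg(taMethod)
  if (min(tb$timestamp) > max(hr$timestamp) ||
      max(tb$timestamp) < min(hr$timestamp))
    stop("no temporal overlap between heart-rate and Tb streams")
  taNum <- as.numeric(ta$timestamp)
  out <- lapply(split(tb, tb$individual), function(d) {
    hri <- hr[hr$individual == d$individual[1L], , drop = FALSE]
    tbNum <- as.numeric(d$timestamp)
    fh <- if (nrow(hri)) {
      s <- smoothRate(
        heartRateSeries(as.numeric(hri$timestamp), hri$fh),
        window = smoothWindow, at = tbNum)
      s@bpm
    } else rep(NA_real_, nrow(d))
    taMatch <- if (taMethod == "nearest") {
      idx <- vapply(tbNum, function(t) which.min(abs(taNum - t)),
                    integer(1))
      ta$ta[idx]
    } else approx(taNum, ta$ta, xout = tbNum, rule = 2)$y
    data.frame(timestamp = d$timestamp, individual = d$individual,
               fh = fh, tb = d$tb, ta = taMatch, tdiff = d$tb - taMatch,
               scotophase = scotophaseAnnotation(d$timestamp, dusk, dawn),
               tb_below_ta = d$tb < taMatch)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$individual, out$timestamp), , drop = FALSE]
}

#' Classify low-energy-state records by heart-rate quantile
#'
#' The threshold is the pooled (default) or per-individual `quantile`
#' quantile of the observed heart rates (type-7 convention); records at
#' or below it are flagged as low state. Pooling matches the definition
#' of the low state as the lowest fraction of all observed values.
#'
#' @param records field records from [syncStreams()] (needs `fh`).
#' @param quantile quantile defining the low state (default 0.10).
#' @param perIndividual compute thresholds per individual instead.
#' @return A list: `records` (input plus `low_state` flag),
#'   `threshold` (named per individual when `perIndividual`),
#'   `hours` (hours of day containing at least one flagged record).
#' @export
classifyLowState <- function(records, quantile = 0.10,
                             perIndividual = FALSE) {
  fhOk <- is.finite(records$fh)
  if (sum(fhOk) < 10L) stop("need at least 10 records with heart rate")
  if (perIndividual) {
    thr <- tapply(records$fh[fhOk], records$individual[fhOk],
                  stats::quantile, probs = quantile, type = 7,
                  names = FALSE)
    low <- fhOk & records$fh <= thr[as.character(records$individual)]
  } else {
    thr <- stats::quantile(records$fh[fhOk], quantile, type = 7,
                           names = FALSE)
    low <- fhOk & records$fh <= thr
  }
  records$low_state <- low
  hours <- sort(unique(as.numeric(format(records$timestamp[low], "%H"))))
  list(records = records, threshold = thr, hours = hours)
}

#' Hourly summaries of heart rate and body temperature
#'
#' Per hour-of-day means, standard deviations and counts for `fh` and
#' `tb`, plus the fraction of records flagged as low state when the
#' flag is present. Hours without data are reported with `NA` means and
#' zero counts, never as zero means.
#'
#' @param records field records (optionally with `low_state`).
#' @return A data.frame with one row per hour 0--23.
#' @export
hourlySummary <- function(records) {
  if (!nrow(records)) stop("records must be non-empty")
  hour <- as.numeric(format(records$timestamp, "%H"))
  out <- do.call(rbind, lapply(0:23, function(h) {
    d <- records[hour == h, , drop = FALSE]
    fh <- d$fh[is.finite(d$fh)]
    tb <- d$tb[is.finite(d$tb)]
    data.frame(hour = h,
               mean_fh = if (length(fh)) mean(fh) else NA_real_,
               sd_fh = if (length(fh) > 1) sd(fh) else NA_real_,
               n_fh = length(fh),
               mean_tb = if (length(tb)) mean(tb) else NA_real_,
               sd_tb = if (length(tb) > 1) sd(tb) else NA_real_,
               n_tb = length(tb),
               frac_low = if ("low_state" %in% names(d) && nrow(d))
                 mean(d$low_state, na.rm = TRUE) else NA_real_)
  }))
  out
}

#' Field regressions of temperature and heart rate
#'
#' Random-intercept fits (via [fitRandomIntercept()]; there is no
#' second fitting path) of `tb ~ ta`, `fh ~ tb` and `fh ~ tdiff`, each
#' on its own listwise-complete rows, with the likelihood-ratio
#' chi-squared against the intercept-only model, slope, and
#' marginal/conditional R2 collected in one table.
#'
#' @param records field records from [syncStreams()] with >= 2
#'   individuals.
#' @return A list with `table` (model, n, slope, chi2, df, p, r2m, r2c)
#'   and `fits`.
#' @export
fieldRegressions <- function(records) {
  specs <- list(c(y = "tb", x = "ta"), c(y = "fh", x = "tb"),
                c(y = "fh", x = "tdiff"))
  fits <- list()
  rows <- list()
  for (s in specs) {
    lab <- paste(s[["y"]], "~", s[["x"]])
    d <- records[is.finite(records[[s[["y"]]]]) &
                   is.finite(records[[s[["x"]]]]), , drop = FALSE]
    fit <- fitRandomIntercept(d, s[["x"]], s[["y"]], "ML")
    null <- fitRandomIntercept(d, character(0), s[["y"]], "ML")
    lt <- lrTest(null, fit)
    fits[[lab]] <- fit
    rows[[lab]] <- data.frame(model = lab, n = fit@nObs,
                              slope = fit@beta[[s[["x"]]]],
                              chi2 = lt$chi2, df = lt$df, p = lt$p,
                              r2m = fit@r2m, r2c = fit@r2c)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Predict field energy expenditure from heart rate
#'
#' Applies a heart-rate calibration to every field record and
#' integrates daily totals over the observed coverage only: each record
#' contributes its rate over one nominal cadence interval, gaps are
#' never imputed, and a day with more than `gapThreshold` missing
#' coverage is flagged unreliable.
#'
#' @param records field records with `timestamp`, `individual`, `fh`.
#' @param fit a [ModelFit] or [calibrationCoefficients()]; its unit tag
#'   must be `"kJ/h"` or `"kJ/d"` so the temporal integration is
#'   defined.
#' @param gapThreshold maximum tolerated missing fraction of the day.
#' @return A list with `series` (per-record expenditure rate) and
#'   `daily` (per individual x date: total kJ, coverage fraction,
#'   `reliable` flag).
#' @export
predictFieldExpenditure <- function(records, fit, gapThreshold = 0.5) {
  ok <- is.finite(records$fh)
  rate <- rep(NA_real_, nrow(records))
  pred <- predictExpenditure(records$fh[ok], fit)
  unit <- attr(pred, "unit")
  if (is.na(unit) || !unit %in% c("kJ/h", "kJ/d"))
    stop("calibration unit tag must be resolved to kJ/h or kJ/d ",
         "before integrating")
  rate[ok] <- pred
  perHour <- if (unit == "kJ/h") rate else rate / 24
  series <- data.frame(timestamp = records$timestamp,
                       individual = records$individual,
                       fh = records$fh, rate = rate,
                       rate_kj_h = perHour)
  key <- interaction(records$individual,
                     format(records$timestamp, "%Y-%m-%d"), drop = TRUE)
  daily <- do.call(rbind, lapply(split(seq_len(nrow(records)), key),
                                 function(idx) {
    idx <- idx[is.finite(perHour[idx])]
    if (!length(idx)) return(NULL)
    tt <- as.numeric(records$timestamp[idx])
    cadence <- if (length(tt) > 1) median(diff(sort(tt))) else NA_real_
    if (!is.finite(cadence)) cadence <- 60
    covered <- length(idx) * cadence            # seconds
    total <- sum(perHour[idx]) * cadence / 3600 # kJ
    data.frame(individual = records$individual[idx[1L]],
               date = format(records$timestamp[idx[1L]], "%Y-%m-%d"),
               total_kj = total, coverage = covered / 86400,
               reliable = covered / 86400 >= 1 - gapThreshold)
  }))
  rownames(daily) <- NULL
  list(series = series, daily = daily)
}
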