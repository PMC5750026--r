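# Open-flow respirometry processing: baseline correction against the
# empty reference chamber, gas-exchange equations, energy conversion,
# alignment with body-temperature / heart-rate streams, and extraction
# of minimum (torpor-like) and steady metabolic states.

# Linear interpolation with linear (not constant) extrapolation beyond
# the outermost knots, so a linear drift is removed exactly even for
# samples outside the first/last baseline-period midpoints.
.interpExtrap <- function(x, y, xout) {
  out <- approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1L]
  hi <- xout > x[n]
  if (any(lo))
    out[lo] <- y[1L] + (y[2L] - y[1L]) / (x[2L] - x[1L]) * (xout[lo] - x[1L])
  if (any(hi))
    out[hi] <- y[n] + (y[n] - y[n - 1L]) / (x[n] - x[n - 1L]) *
      (xout[hi] - x[n])
  out
}

# Contiguous baseline periods from the logical mask.
.baselinePeriods <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) starts[i]:ends[i])
}

#' Baseline-correct a respirometry trace
#'
#' Replaces the nominal incurrent fractions by the reference-chamber
#' signal interpolated across the recording: each baseline period
#' contributes its mean excurrent reading at its mid-time, and the
#' incurrent CO2/O2 fractions for animal periods are linearly
#' interpolated between those means (constant beyond the first/last
#' period). Linear analyzer drift is thereby removed exactly. With a
#' single baseline period a constant baseline is used (message logged);
#' with none, fixed incurrent fractions must be supplied.
#'
#' @param trace a [RespirometryTrace].
#' @param incurrent optional `c(co2 = , o2 = )` fallback when the trace
#'   has no baseline periods.
#' @return The corrected [RespirometryTrace] (`corrected` flag set).
#' @export
baselineCorrect <- function(trace, incurrent = NULL) {
  stopifnot(is(trace, "RespirometryTrace"))
  periods <- .baselinePeriods(trace@baselineMask)
  if (!length(periods)) {
    if (is.null(incurrent))
      stop("no baseline periods: supply fixed incurrent fractions via ",
           "'incurrent = c(co2 =, o2 =)'")
    fico2 <- rep(incurrent[["co2"]], length(trace@time))
    fio2 <- rep(incurrent[["o2"]], length(trace@time))
  } else if (length(periods) == 1L) {
    message("single baseline period: using a constant baseline ",
            "(zero-drift assumption)")
    idx <- periods[[1L]]
    fico2 <- rep(mean(trace@feco2[idx]), length(trace@time))
    fio2 <- rep(mean(trace@feo2[idx]), length(trace@time))
  } else {
    mid <- vapply(periods, function(idx) mean(trace@time[idx]), numeric(1))
    bco2 <- vapply(periods, function(idx) mean(trace@feco2[idx]), numeric(1))
    bo2 <- vapply(periods, function(idx) mean(trace@feo2[idx]), numeric(1))
    fico2 <- .interpExtrap(mid, bco2, trace@time)
    fio2 <- .interpExtrap(mid, bo2, trace@time)
  }
  out <- trace
  out@fico2 <- fico2
  out@fio2 <- fio2
  out@corrected <- TRUE
  out
}

#' Rate of CO2 production from gas fractions
#'
#' Two forms of the open-flow CO2 equation are available. The
#' `"printed"` variant evaluates
#' `VCO2 = (FeCO2 - FiCO2) * FR / (1 - FeCO2 * (1 - (1 - RER)))`,
#' whose denominator simplifies to `1 - FeCO2 * RER`; the `"textbook"`
#' variant is the standard dried-air form
#' `VCO2 = FR * (FeCO2 - FiCO2) / (1 - FeCO2 * (1 - 1/RER))`. At the
#' sub-percent CO2 concentrations typical of small-animal work the two
#' agree to within 0.5\%; both are implemented because the published
#' denominators differ and which was computed cannot be recovered from
#' the text.
#'
#' @param feco2,fico2 excurrent and incurrent CO2 fractions.
#' @param fr flow rate, ml min-1 (STP-corrected).
#' @param rer respiratory exchange ratio, in (0.7, 1].
#' @param variant `"printed"` (default) or `"textbook"`.
#' @return CO2 production in ml min-1.
#' @examples
#' computeVCO2(0.001, 0, 300, 0.8)                      # 0.3002402
#' computeVCO2(0.001, 0, 300, 0.8, variant = "textbook") # 0.2999250
#' @export
computeVCO2 <- function(feco2, fico2, fr, rer = 0.8,
                        variant = c("printed", "textbook")) {
  variant <- match.arg(variant)
  if (any(rer <= 0.7 | rer > 1)) stop("rer must lie in (0.7, 1]")
  denom <- if (variant == "printed")
    1 - feco2 * (1 - (1 - rer)) else 1 - feco2 * (1 - 1 / rer)
  if (any(denom <= 0)) stop("non-positive denominator in the CO2 equation")
  (feco2 - fico2) * fr / denom
}

#' Rate of O2 consumption from gas fractions (CO2-scrubbed stream)
#'
#' O2 is measured after the excurrent air is scrubbed of CO2, so the
#' CO2-absorbed configuration applies:
#' `VO2 = FR * (FiO2 - FeO2) / (1 - FiO2)`.
#'
#' @param feo2,fio2 excurrent and incurrent O2 fractions.
#' @param fr flow rate, ml min-1.
#' @return O2 consumption in ml min-1.
#' @examples
#' computeVO2(0.2090, 0.2095, 300)   # 0.18975
#' @export
computeVO2 <- function(feo2, fio2, fr) {
  if (any(fio2 >= 1)) stop("fio2 must be below 1")
  fr * (fio2 - feo2) / (1 - fio2)
}

#' Respiratory exchange ratio from paired gas series
#'
#' @param vco2,vo2 aligned CO2-production and O2-consumption series,
#'   ml min-1.
#' @param method `"mean-of-ratios"` (mean of pointwise VCO2/VO2,
#'   default) or `"ratio-of-means"`.
#' @param mask optional logical subset (e.g. a steady-state mask).
#' @return The exchange ratio.
#' @export
computeRER <- function(vco2, vo2, method = c("mean-of-ratios",
                                             "ratio-of-means"),
                       mask = NULL) {
  method <- match.arg(method)
  if (!is.null(mask)) {
    vco2 <- vco2[mask]
    vo2 <- vo2[mask]
  }
  ok <- is.finite(vco2) & is.finite(vo2) & vo2 > 0
  if (!any(ok)) stop("no valid pairs: vo2 must be positive somewhere")
  if (method == "mean-of-ratios") mean(vco2[ok] / vo2[ok]) else
    mean(vco2[ok]) / mean(vo2[ok])
}

#' Convert CO2 production to metabolic power
#'
#' Uses the standard equivalence of 25.0 J per ml CO2:
#' kJ h-1 = VCO2 x 25.0 x 60 / 1000 and
#' W g-1 = VCO2 x 25.0 / 60 / mass.
#'
#' @param vco2 CO2 production, ml min-1 (non-negative).
#' @param massG body mass in grams; the 10.5 g default is the mean mass
#'   of the study animals and is intended for synthetic runs.
#' @param jouleEquiv energy equivalence, J per ml CO2.
#' @return A data.frame with columns `kj_h` and `w_g`.
#' @export
vco2ToPower <- function(vco2, massG = 10.5, jouleEquiv = 25.0) {
  if (any(vco2 < 0, na.rm = TRUE)) stop("vco2 must be non-negative")
  if (massG <= 0) stop("massG must be positive")
  data.frame(kj_h = vco2 * jouleEquiv * 60 / 1000,
             w_g = vco2 * jouleEquiv / 60 / massG)
}

#' Full gas-exchange processing of a corrected trace
#'
#' Applies [computeVCO2()], [computeVO2()] and [vco2ToPower()] to the
#' animal-period samples of a baseline-corrected trace and aggregates
#' to the gas sampling cadence.
#'
#' @param trace a baseline-corrected [RespirometryTrace] (traces that
#'   have not been corrected are corrected first when possible).
#' @param rer respiratory exchange ratio.
#' @param massG body mass, g.
#' @param variant CO2 equation variant, see [computeVCO2()].
#' @param sampleSeconds gas sampling cadence for the output series
#'   (default 300 s, i.e. 5-min samples); `NULL` keeps the native
#'   resolution.
#' @return A [MetabolicSeries] (animal periods only).
#' @export
computeMetabolicSeries <- function(trace, rer = 0.8, massG = 10.5,
                                   variant = "printed",
                                   sampleSeconds = 300) {
  stopifnot(is(trace, "RespirometryTrace"))
  if (!trace@corrected) trace <- baselineCorrect(trace)
  keep <- !trace@baselineMask
  vco2 <- computeVCO2(trace@feco2[keep], trace@fico2[keep],
                      trace@flowRate[keep], rer, variant)
  vo2 <- computeVO2(trace@feo2[keep], trace@fio2[keep],
                    trace@flowRate[keep])
  tt <- trace@time[keep]
  if (!is.null(sampleSeconds)) {
    bin <- floor(tt / sampleSeconds)
    agg <- function(v) as.numeric(tapply(v, bin, mean))
    tt <- (as.numeric(names(table(bin))) + 1) * sampleSeconds
    vco2 <- agg(vco2)
    vo2 <- agg(vo2)
  }
  vco2 <- pmax(vco2, 0)
  vo2 <- pmax(vo2, 0)
  p <- vco2ToPower(vco2, massG)
  new("MetabolicSeries", time = tt, vco2 = vco2, vo2 = vo2,
      mrKjH = p$kj_h, mrWg = p$w_g, massG = massG)
}

#' Align body temperature, heart rate and gas samples
#'
#' Each body-temperature timestamp receives the trailing 60-s mean
#' heart rate; each gas sample (cadence inferred from the metabolic
#' series, typically 5 min against 1-min body temperature, i.e. five
#' Tb/fH pairs per sample) receives the mean of the Tb/fH pairs falling
#' in its sampling interval. Both granularities are returned. A cadence
#' mismatch is not forced: the per-sample pair count is reported as is.
#'
#' @param tbSeries data.frame with `time` (s) and `tb` (degrees C);
#'   optionally `ta`.
#' @param hrSeries a [HeartRateSeries] (raw counts; trailing smoothing
#'   is applied here).
#' @param metSeries a [MetabolicSeries].
#' @param individual individual label for the output records.
#' @param smoothWindow trailing heart-rate window, seconds.
#' @return A list with `perTb` (one row per Tb timestamp: `time`, `fh`,
#'   `tb`, `ta`, `tdiff`, `mr_kj_h`, `mr_w_g`, `individual`) and
#'   `perSample` (one row per gas sample with the pair count `n_pairs`).
#' @export
alignMeasures <- function(tbSeries, hrSeries, metSeries,
                          individual = "ind01", smoothWindow = 60) {
  stopifnot(is(hrSeries, "HeartRateSeries"), is(metSeries, "MetabolicSeries"))
  if (max(tbSeries$time) < min(metSeries@time) ||
      min(tbSeries$time) > max(metSeries@time))
    stop("no overlapping time coverage between Tb and gas samples")
  sm <- smoothRate(hrSeries, window = smoothWindow, at = tbSeries$time)
  ta <- if ("ta" %in% names(tbSeries)) tbSeries$ta else
    rep(NA_real_, nrow(tbSeries))
  cadence <- if (length(metSeries@time) > 1L)
    median(diff(metSeries@time)) else
      diff(range(tbSeries$time)) + 1
  mrAt <- approx(metSeries@time, metSeries@mrKjH, xout = tbSeries$time,
                 rule = 2)$y
  wgAt <- approx(metSeries@time, metSeries@mrWg, xout = tbSeries$time,
                 rule = 2)$y
  perTb <- data.frame(time = tbSeries$time, fh = sm@bpm, tb = tbSeries$tb,
                      ta = ta, tdiff = tbSeries$tb - ta, mr_kj_h = mrAt,
                      mr_w_g = wgAt, individual = individual)
  perSample <- do.call(rbind, lapply(seq_along(metSeries@time), function(i) {
    tEnd <- metSeries@time[i]
    sel <- tbSeries$time > tEnd - cadence & tbSeries$time <= tEnd
    data.frame(time = tEnd, n_pairs = sum(sel),
               fh = if (any(sel)) mean(sm@bpm[sel], na.rm = TRUE) else NA_real_,
               tb = if (any(sel)) mean(tbSeries$tb[sel]) else NA_real_,
               ta = if (any(sel)) mean(ta[sel]) else NA_real_,
               mr_kj_h = metSeries@mrKjH[i], mr_w_g = metSeries@mrWg[i],
               individual = individual)
  }))
  perSample$tdiff <- perSample$tb - perSample$ta
  list(perTb = perTb, perSample = perSample)
}

#' Minimum (torpor-like) metabolic states per individual
#'
#' For each individual, selects the records whose metabolic rate lies
#' at or below that individual's `quantile` quantile (linear
#' interpolation, type-7 convention) and summarizes their MR, heart
#' rate and body temperature. The 30\%-quantile mean, used when
#' comparing resting states against basal rates, is reported alongside.
#'
#' @param aligned data.frame with columns `individual`, `mr_kj_h` (or a
#'   column named by `mrColumn`), and optionally `fh`, `tb`, `mr_w_g`.
#' @param quantile quantile defining the minimum state (default 0.10).
#' @param mrColumn name of the MR column used for ranking.
#' @param minRecords individuals with fewer records are skipped with a
#'   warning.
#' @return A list with `records` (the selected rows) and `summary` (one
#'   row per individual: threshold, means, and the 30\%-quantile MR
#'   means).
#' @export
minimumStates <- function(aligned, quantile = 0.10, mrColumn = "mr_kj_h",
                          minRecords = 10) {
  stopifnot(mrColumn %in% names(aligned))
  inds <- unique(as.character(aligned$individual))
  recs <- list()
  rows <- list()
  for (id in inds) {
    d <- aligned[as.character(aligned$individual) == id &
                   is.finite(aligned[[mrColumn]]), , drop = FALSE]
    if (nrow(d) < minRecords) {
      warning("individual ", id, " has fewer than ", minRecords,
              " records: skipped")
      next
    }
    thr <- stats::quantile(d[[mrColumn]], quantile, type = 7, names = FALSE)
    thr30 <- stats::quantile(d[[mrColumn]], 0.30, type = 7, names = FALSE)
    sel <- d[[mrColumn]] <= thr
    sel30 <- d[[mrColumn]] <= thr30
    recs[[id]] <- d[sel, , drop = FALSE]
    getMean <- function(col, subset) if (col %in% names(d))
      mean(d[[col]][subset], na.rm = TRUE) else NA_real_
    rows[[id]] <- data.frame(
      individual = id, n = nrow(d), n_selected = sum(sel),
      threshold = thr, mean_mr = mean(d[[mrColumn]][sel]),
      mean_fh = getMean("fh", sel), mean_tb = getMean("tb", sel),
      mean_mr_q30 = mean(d[[mrColumn]][sel30]),
      mean_w_g_q30 = getMean("mr_w_g", sel30))
  }
  if (!length(rows)) stop("no individual has enough records")
  list(records = do.call(rbind, recs), summary = do.call(rbind, rows))
}

#' Steady-state mask from rolling variability
#'
#' Marks samples where the rolling coefficient of variation of the
#' metabolic rate over `window` samples falls below `cvThreshold`
#' (default 10\% over four 5-min samples, i.e. 20 min).
#'
#' @param metSeries a [MetabolicSeries] (or a numeric MR vector).
#' @param window rolling window length in samples (>= 3).
#' @param cvThreshold coefficient-of-variation threshold.
#' @return A logical vector along the series.
#' @export
steadyStateMask <- function(metSeries, window = 4, cvThreshold = 0.10) {
  mr <- if (is(metSeries, "MetabolicSeries")) metSeries@mrKjH else
    as.numeric(metSeries)
  if (window < 3) stop("window must span at least 3 samples")
  cv <- zoo::rollapply(mr, window,
                       function(v) stats::sd(v) / mean(v),
                       fill = NA, align = "center", partial = TRUE)
  out <- is.finite(cv) & cv < cvThreshold
  out
}
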