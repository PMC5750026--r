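# Body-temperature forward model: first-order relaxation toward the
# ambient temperature plus a metabolic heat offset, integrated at 1-s
# internal steps (exact exponential updates per step) and decimated to
# the 1-min output cadence. A closed-form solution exists for constant
# inputs and is used as the test oracle.

#' Simulate body temperature from metabolic rate and ambient temperature
#'
#' Integrates dTb/dt = kCool (Ta + heatGain * MR - Tb) with per-step
#' exact exponential updates at `internalStep` resolution, holding MR
#' and Ta constant within each step, and returns Tb at a 1-min cadence.
#' With constant inputs Tb converges monotonically to
#' `Ta + heatGain * MR`; after a step drop in MR, Tb is continuous and
#' follows at the slower rate set by `kCool`, reproducing the observed
#' lag of body temperature behind metabolic state.
#'
#' @param thermal a [thermalSpec()].
#' @param mrTraj data.frame `time` (s), `mr_kj_h`; linearly interpolated.
#' @param taSeries data.frame `time` (s), `ta` (degrees C); linearly
#'   interpolated. Must share a time base with `mrTraj` (overlapping
#'   span).
#' @param internalStep integration step, seconds.
#' @param outputStep output cadence, seconds (default one minute).
#' @return data.frame with `time` and `tb`.
#' @export
simulateBodyTemperature <- function(thermal, mrTraj, taSeries,
                                    internalStep = 1, outputStep = 60) {
  stopifnot(is(thermal, "ThermalSpec"))
  t0 <- max(min(mrTraj$time), min(taSeries$time))
  t1 <- min(max(mrTraj$time), max(taSeries$time))
  if (t1 <= t0)
    stop("mrTraj and taSeries do not share a time base (no overlap)")
  tGrid <- seq(t0, t1, by = internalStep)
  mr <- approx(mrTraj$time, mrTraj$mr_kj_h, xout = tGrid, rule = 2)$y
  ta <- approx(taSeries$time, taSeries$ta, xout = tGrid, rule = 2)$y
  equil <- ta + thermal@heatGain * mr
  kPerSec <- thermal@kCool / 60
  decay <- exp(-kPerSec * internalStep)
  tb <- numeric(length(tGrid))
  tb[1L] <- thermal@tbInit
  for (i in seq_along(tGrid)[-1L])
    tb[i] <- equil[i - 1L] + (tb[i - 1L] - equil[i - 1L]) * decay
  keep <- which((tGrid - t0) %% outputStep == 0)
  data.frame(time = tGrid[keep], tb = tb[keep])
}
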