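---
title: "Methods: heart-rate telemetry, respirometry energetics and torpor inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate telemetry, respirometry energetics and torpor inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiotel)
```

`physiotel` turns three raw physiological data classes — transmitter
audio, open-flow gas traces, and field telemetry tables — into
energetic inference for small endotherms that use shallow daily
torpor. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## 1. Heartbeat detection from transmitter audio

External heart-rate transmitters emit a continuous carrier tone that
is gated off briefly by each cardiac muscle potential, so a heartbeat
appears in the received audio as an amplitude *interruption*. The
detector therefore works on downward excursions of the amplitude
envelope — the alternative reading (beats as energy bursts) does not
match the transmitter's design and is not implemented.

The chain is: estimate the carrier frequency (Welch-averaged
periodogram peak; a peak must exceed the in-band median power by
`carrierMargin`, default 30, or a "no carrier" error is raised);
band-limit with a linear-phase Hamming FIR (`firLength` 1500 taps by
default, anywhere in 1500–2000 gives results identical to within 2%,
which the test suite checks; group delay is compensated exactly so
event times are unshifted); form an RMS envelope (2-ms smoothing, well
below the 15-ms pulse width and above the carrier period); and score a
beat for each excursion below `envelopeThreshold` (default 0.5) times
a rolling-median carrier level (2-s span, robust to slow signal
fading). Excursions shorter than `minEventDuration` (4 ms) are
interference; events closer than the `refractory` interval (40 ms) are
merged, which caps the detectable rate at 1500 bpm — comfortably above
the 1068 bpm observed maximum for roosting molossid bats.

Events are tallied over non-overlapping windows of `windowLen` = 500
samples, the counting resolution of the original seewave-style scoring:
96 windows s⁻¹ at 48 kHz, 88.2 at 44.1 kHz. No recording sample rate
is hard-coded; the generator and detector take it as a parameter, with
48 kHz as the default.

### Kernel-density rate filtering

Heart rate is strongly autocorrelated, so isolated static-induced rate
values sit in low-density regions of the rate distribution. The filter
estimates a Gaussian KDE of the bpm values (Silverman's rule unless a
bandwidth in bpm is given) and flags values outside the 90% region.
"Outside the 90% quantile" admits two readings, and both are
implemented: the default flags points below the density level
enclosing 90% of the KDE mass (highest-density region), a config
switch (`kdeMethod = "interval"`) instead keeps the central 90%
probability interval of values. The HDR reading can in principle keep
a distant value that happens to sit in a secondary density bump while
trimming a cluster tail, so only the *value range* is guaranteed never
to widen under HDR; the interval reading keeps one contiguous band and
additionally can never widen the interquartile range. Filtering is
whole-recording by default; the original work does not state whether a
sliding context was used.

Hand-scoring of respirometry recordings (where the PIT-tag reader
interferes) is emulated by its *sampling scheme* only: count beats in
the first 10 s of each minute and multiply by six. The counting itself
reuses the automated detector — the scheme, not human counting skill,
is the method. The emulation reproduces the scheme's documented bias:
a minute whose first 10 s are silent scores 0 bpm.

## 2. Respirometry

Gas fractions are baseline-corrected against the empty reference
chamber: each baseline period contributes its mean excurrent reading
at its mid-time, and incurrent fractions for animal periods are
linearly interpolated between those means, with *linear* extrapolation
beyond the outermost midpoints so a linear analyzer drift cancels
exactly (the test suite verifies cancellation to 1e-6 on simulated
drift). With a single baseline period a constant baseline is assumed
and logged; with none, fixed incurrent fractions must be supplied.

CO₂ production uses, verbatim, the published equation whose
denominator simplifies to 1 − FeCO₂·RER (`variant = "printed"`,
default). This conflicts with the standard dried-air form
1 − FeCO₂(1 − 1/RER) (`variant = "textbook"`); which one was actually
computed cannot be recovered from the text, so both are implemented
and neither is silently "corrected". Their relative divergence is
≈ FeCO₂ (1/RER − RER), i.e. 0.11% at FeCO₂ = 0.001 and 0.53% at
FeCO₂ = 0.005 — note the often-quoted "within 0.5% below 0.5% CO₂"
bound is marginally exceeded exactly at the endpoint. O₂ consumption
uses the CO₂-scrubbed configuration V̇O₂ = FR(FiO₂ − FeO₂)/(1 − FiO₂),
the standard form for a Drierite + Ascarite analyzer train. Energy
conversion uses 25.0 J ml⁻¹ CO₂; mass-specific rates default to the
10.5 g mean study mass for synthetic runs and should use measured
masses otherwise. No washout (Z-transform) response correction is
applied — none is described for the original system — so 5-min
sampling through a ~2 l chamber at 300 ml min⁻¹ is a known smoothing
source.

Alignment follows the measurement cadences: each 1-min body
temperature receives the trailing 60-s mean heart rate (causal window,
not centered), and each 5-min gas sample receives the mean of the five
Tb/f_H pairs in its interval. Other cadences are reported as-is
(`n_pairs`), never forced to five. Minimum metabolic states are the
records at or below the per-individual 10% quantile of MR; quantiles
use R's type-7 (linear interpolation) convention throughout, which the
source does not specify — the choice is documented rather than silent.
Steady states are marked where the rolling coefficient of variation of
MR falls below 10% over 4 consecutive 5-min samples (20 min); the
original steady-state criterion is unstated, so this conservative rule
is a package choice.

## 3. Calibration

The mixed models are linear with identity link — the response is a
continuous metabolic rate and every published fit is a linear
equation, so "GLMM" resolves to an LMM with a per-individual random
intercept. Fits are by maximum likelihood whenever AICc comparison or
likelihood-ratio testing is intended (REML likelihoods are not
comparable across fixed-effect structures; REML remains available for
variance reporting). The AICc parameter count is fixed effects + 2
variance components, a documented convention. Missing values are
deleted listwise per fit with the used `n` reported, since the field
fits legitimately run on very different row counts. Marginal and
conditional R² follow the variance-components decomposition:
σ²_f/(σ²_f+σ²_u+σ²_e) and (σ²_f+σ²_u)/(σ²_f+σ²_u+σ²_e), with σ²_f the
variance of the fixed-effect linear predictor over the data. Model
selection fits all candidates on identical listwise-complete rows and
ranks by AICc with ties broken by fewer parameters; the default
candidate set is the three single predictors, all pairs, and the
f_H × temperature interactions (the original supplementary candidate
list is not published, so the set is configurable).

One selection property deserves a note: when the candidate set
contains strict supersets of the true model, any AIC-type criterion
retains the true model only with asymptotic probability
P(χ²₁ < 2) ≈ 0.84 per spurious predictor. A "selects the generating
model ≥ 90% of the time" guarantee is therefore only meaningful — and
only tested — for the substantive single-predictor comparison
(f_H vs T_b vs T_diff), which is the scientific question here; against
a superset candidate the package instead verifies that a pure-noise
predictor raises AICc in expectation.

The published best-fit calibration, expenditure = 0.00106 f_H +
0.0527, is printed in kJ d⁻¹, yet its predictions over the observed
59–999 bpm range span 0.115–1.11 — numerically matching the kJ h⁻¹ MR
range (0.075–1.245 kJ h⁻¹) reported from the same trials, a ~24×
discrepancy that cannot be resolved from the text. The package
therefore carries an explicit unit tag on every calibration and fit,
`calibrationCoefficients()` refuses to default the unit, and no
conversion is ever applied silently.

## 4. Field analysis

Body-temperature observations define the record grid; heart rate is
matched by the trailing 60-s smooth and ambient temperature by the
nearest 15-min station reading (linear interpolation optional; no
microclimate correction is attempted because the station sat hundreds
of meters from the roosts and a correction would be uncheckable).
Records with T_b < T_a are retained and flagged — they genuinely occur
in cool roost microhabitats. Low-energy states use the *pooled* 10%
heart-rate quantile by default, matching the definition "lowest 10% of
observed values" (per-individual thresholds are a switch; note the
respirometry minimum-state quantile stays per-individual by
definition). Scotophase defaults to 18:15–06:15, closed at dusk and
open at dawn — an approximation for lowland Panama documented as such.
Field regressions (T_b ~ T_a, f_H ~ T_b, f_H ~ T_diff) reuse the
calibration module's fitting path; there is no second implementation
to drift out of sync. Daily expenditure integrates each record over
one nominal cadence interval of observed coverage: gaps are never
imputed, totals scale linearly with coverage, and a day more than 50%
missing is flagged unreliable.

## 5. The synthetic-data generator

The generator exists so that every downstream stage has an acceptance
surface with known ground truth. Its defaults encode the study
conditions:

* **Audio** (`signalSpec`): unit carrier at 1500 Hz, 48 kHz sampling,
  15-ms rectangular suppression of depth 0.9 with raised-cosine edges
  (20% of the pulse each side) per beat, Gaussian noise (s.d. 0.05),
  optional Poisson-timed 20-ms wide-band static bursts. Beats are
  placed deterministically where the integral of the rate trajectory
  crosses half-integers, so the count over any interval matches the
  analytic integral to within one beat and no pulse straddles the
  recording boundary. Rates are validated against a 0–1200 bpm
  envelope around the observed 58–1068 bpm field range. Pulse overlap
  (width × rate/60 ≥ 1) is rejected explicitly, never clipped. The
  beat shape is the simplest one that exercises envelope detection;
  real transmitter pulses are not square, and no RF propagation,
  electronics or Doppler effects are modeled.
* **Respirometry** (`chamberSpec`): 300 ml min⁻¹ flow, incurrent
  fractions 0.0004/0.2095, 5-min baselines at the start, end and every
  30 min, optional linear analyzer drift and Gaussian fraction noise.
  The forward model inverts the same printed CO₂ equation the analysis
  evaluates, so the noise-free round trip is exact by construction —
  passing it validates the plumbing, not the equation. The
  two-temperature protocol generator (`simulateMetabolicProtocol`)
  holds resting plateaus of 0.131 kJ h⁻¹ at 28 °C and 0.160 kJ h⁻¹ at
  32 °C (the reported steady-state means) with a slow
  Ornstein–Uhlenbeck fluctuation of s.d. 0.019 kJ h⁻¹ — sized so the
  mean of the lowest 30% of samples sits at 0.00314 W g⁻¹ at 10.5 g,
  the reported resting quantile level — plus occasional ~1 kJ h⁻¹
  arousal excursions.
* **Body temperature** (`thermalSpec`): first-order dynamics
  dT_b/dt = k_cool(T_a + heatGain·MR − T_b), integrated with exact
  per-step exponential updates at 1-s resolution and decimated to the
  1-min output cadence, so the constant-input closed form is
  reproduced to machine precision. Defaults k_cool = 0.03 min⁻¹ (~33
  min time constant) and heatGain = 40 °C/(kJ h⁻¹) reproduce the
  qualitative observation that heart rate drops into a low state
  quickly while body temperature follows slowly. This is a one-pool
  caricature: no regional heterothermy, no evaporative pathways.
* **Calibration tables** (`mixedModelSpec`): y = intercept + slope·x +
  u_i + e_ij with u ~ N(0, σ_u²), e ~ N(0, σ_e²), x uniform. Defaults
  are the published calibration coefficients over f_H ∈ [59, 999] bpm
  with σ_u = 0.05 and σ_e = 0.108, chosen from the variance algebra so
  the implied conditional R² is 0.88, the published value; the
  f_H ~ T_b generator uses (14.985, −353.237) over T_b ∈ [28, 37] °C
  with σ_u = 15 and σ_e = 37.7 bpm, implying R²c ≈ 0.55. Companion
  T_b/T_a/T_diff columns are correlated with f_H so temperature-based
  candidate models are fittable rivals, not degenerate ones.
* **Field datasets** (`simulateFieldDataset`): a 36-h record by
  default; diel ambient sinusoid solved so the photophase and
  scotophase means hit 25.87 and 23.74 °C; active heart rate
  100 + Gamma-distributed excess with mean 147 bpm (never below the
  100-bpm active floor); torpor bouts at 70 ± 6 bpm (< 90 bpm, the
  low-state range) covering ~10% of the default record; 40-min
  foraging gaps after dusk; an optional ~1000 bpm post-return
  tachycardia decay. Heart-rate scatter is i.i.d. within state — the
  strong autocorrelation of real heart rate is *not* emulated, so
  passing tests say nothing about temporally correlated noise — and
  all scatter scales with one `noiseScale` knob (0 = deterministic).

Everything stochastic takes a seed; identical spec + seed gives
bit-identical output, which the suite asserts.

## 6. Problem sizes and numerical choices

Simulated problem sizes were chosen to keep each check sharp but
cheap: 10-s audio clips per rate (48 kHz), 2-h gas traces at 1 Hz,
6 × 150 calibration tables with 100 replicates for recovery and
selection experiments, 200 × 1000 for the variance-law check, 36-h
field records. Mean slope recovery at these sizes has relative
standard error well under 1%, so the 10% acceptance bands test
correctness, not luck. FIR lengths are forced odd for an integer group
delay; envelope edges are filled with the nearest computed value;
KDE uses 1024 grid points; a degenerate (zero-bandwidth) rate
distribution skips filtering rather than erroring; the thermal
integrator is exact per step, so its only error is input
interpolation. The quantile convention is type-7 everywhere.

## 7. Known limitations

Real recordings bring transmitter fading, multi-animal interference
and nonstationary static that the burst model only sketches; the
detector's recall/precision figures on clean synthetic audio are upper
bounds. The respirometry round trip shares its gas equation with the
generator by design, so it cannot reveal a transcription error in that
equation — the printed-vs-textbook variant comparison exists precisely
to bound that risk. Calibration is strictly linear and must not be
extrapolated to exercising animals (torpid-to-resting regressions are
known to underestimate active metabolism). Daily expenditure totals
are coverage-weighted sums, not gap-filled estimates. The kJ d⁻¹ vs
kJ h⁻¹ ambiguity of the published calibration is carried, not
resolved; any downstream use must pick a unit explicitly.
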