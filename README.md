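# physiotel

Energetics of small endotherms from heart-rate telemetry and open-flow
respirometry.

Small tropical bats such as Pallas' mastiff bat (*Molossus molossus*)
can enter torpor-like low-energy states while their body temperature
stays high and close to ambient. Where ambient temperature barely
varies, body temperature alone is therefore a poor index of metabolic
state, and heart rate (f_H) — which tracks oxygen delivery directly —
becomes the measurable of choice. `physiotel` implements the full
analysis chain that makes this inference reproducible, plus a
synthetic-data generator that emulates every input class with known
ground truth so each stage is testable without animal recordings.

## What the package computes

**Heartbeat detection.** External heart-rate transmitters emit a
continuous carrier interrupted by each cardiac muscle potential. The
detector band-limits the recording to the carrier with a linear-phase
FIR filter (1500–2000 taps), scores a beat for each amplitude-envelope
excursion below a fraction of the rolling carrier level, tallies events
over non-overlapping 500-sample windows (96 windows s⁻¹ at 48 kHz), and
rejects noisy rate values outside the 90% highest-density region of a
kernel density estimate.

**Respirometry.** Open-flow push-through traces are baseline-corrected
against an empty reference chamber and converted to gas-exchange rates:

    V̇CO₂ = (FeCO₂ − FiCO₂) · FR / (1 − FeCO₂·(1 − (1 − RER)))   ["printed" form]
    V̇O₂  = FR · (FiO₂ − FeO₂) / (1 − FiO₂)                      [CO₂-scrubbed]

with RER = V̇CO₂:V̇O₂ (0.8 by default) and energy via 25.0 J ml⁻¹ CO₂,
giving metabolic rate in kJ h⁻¹ and W g⁻¹. A textbook variant of the
CO₂ denominator, 1 − FeCO₂(1 − 1/RER), is available; the two agree to
within ~0.5% at small-animal concentrations.

**Calibration.** Metabolic rate is regressed on f_H, body temperature
(T_b) and the body–ambient differential (T_diff = T_b − T_a) with
random-intercept linear mixed models per individual (ML fits),
ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with
Nakagawa–Schielzeth marginal/conditional R². The fitted calibration
`expenditure = 0.00106 f_H + 0.0527` is bundled with an explicit unit
tag for prediction.

**Field analysis.** Heart-rate, body-temperature and 15-min ambient
streams are synchronized (trailing 60-s f_H smoothing), low-energy
states are classified by the pooled 10% heart-rate quantile,
summarized hourly and by photoperiod, refit with the same mixed-model
machinery, and converted to daily energy expenditure over the observed
coverage only.

## Worked example

```r
library(physiotel)

## synthesize 10 s of transmitter audio at a true 300 bpm and score it
synth   <- synthesizeTransmitterAudio(signalSpec(noiseSd = 0.05, seed = 1),
                                      constantRate(300, 10))
carrier <- estimateCarrierFrequency(synth$audio)
events  <- detectBeats(bandpassFilter(synth$audio, carrier))
events
#> BeatEvents: 50 events over 960 windows (500 samples each, 96.0 windows/s)
countsToRate(events, aggregation = 10)@bpm
#> [1] 300

## calibrate expenditure on heart rate from a synthetic 6 x 150 dataset
calib <- simulateCalibrationDataset(mixedModelSpec(seed = 1))
sel   <- modelSelection(calib, list("fh", "tb", "tdiff"))
sel$table[, c("model", "aicc", "daicc", "r2m", "r2c")]
#>   model    aicc  daicc    r2m    r2c
#> 1    fh -1333.0    0.0 0.8418 0.8652
#> 2    tb  -468.3  864.7 0.6235 0.6441
#> 3 tdiff  -137.7 1195.3 0.4644 0.4896
predictExpenditure(147, sel$fits[[1]])
#> [1] 0.1805326
#> attr(,"unit")
#> [1] "kJ/d"
```

The detector recovers the generating 300 bpm exactly (50 beats in 10 s
over 960 counting windows); model selection identifies heart rate —
not temperature — as the best predictor of metabolic rate by a wide
AICc margin (ΔAICc > 800), with conditional R² ≈ 0.87; and the fitted
line predicts the roosting-rate expenditure at 147 bpm. A full
simulate → detect → respirometry → calibrate → field run is packaged as
`runPipeline(demoConfig())`, which finishes in a few seconds.

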