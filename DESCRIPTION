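Package: physiotel
Title: Energetics from Heart-Rate Telemetry and Open-Flow Respirometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the energetics of small endotherms from
    physiological telemetry. Implements automated heartbeat counting from
    radio heart-rate transmitter audio (FIR band-pass selection of the
    carrier, envelope interruption detection over fixed sample windows,
    kernel-density outlier rejection), open-flow respirometry processing
    (baseline correction, CO2/O2 gas-exchange equations, energy
    conversion, alignment of gas samples with body-temperature and
    heart-rate streams), calibration of metabolic rate on heart rate and
    temperature predictors with random-intercept linear models, AICc
    model selection and marginal/conditional R-squared, and field
    analyses of daily heterothermy (low-energy-state classification,
    hourly summaries, field regressions, energy-expenditure prediction).
    A synthetic-data generator produces every input class with known
    ground truth so the whole pipeline is testable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    signal,
    lme4,
    zoo,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
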