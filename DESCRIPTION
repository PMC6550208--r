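Package: respstrain
Title: Respiration Rate and Volume from Wearable Strain Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breath-by-breath analysis of respiration recorded with skin-mounted
    piezo-resistive strain sensors on the ribcage and abdomen against a
    continuous spirometer reference. Implements the full pipeline from raw
    voltage and resistance channels to calibrated respiration volume: spike
    removal, flow conversion and integration, breath segmentation at flow
    zero-crossings, per-sensor power-law linearization of resistance excursions,
    a two-compartment (Kono-Mead) multiple-regression calibration model,
    respiration-rate estimation in the time and frequency domains,
    accelerometer-guided motion-artifact filtering, spirometry metrics (FEV1,
    FVC, FEV1 percent), and method-agreement statistics (Bland-Altman limits of
    agreement, Lin's concordance correlation). Includes a synthetic-recording
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    zoo,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
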