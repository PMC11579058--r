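Package: scicpms
Title: Single-Cell ICP-MS Signal Processing and Per-Cell Mass Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for time-resolved single-cell inductively coupled
    plasma mass spectrometry (SC-ICP-MS). Detects single-cell ionisation
    events in dwell-resolved count traces by iterative Poisson-statistics
    thresholding (mean + k*SD), estimates transport efficiency by the pulse
    frequency and particle size methods, converts net event counts into
    element mass per cell (fg) through dissolved-standard calibration with
    internal-standard drift correction, computes dissolved and per-event mass
    limits of detection, and characterises population heterogeneity with
    kernel density curves, summary statistics and bootstrap comparisons. A
    fully seed-deterministic synthetic trace generator (Poissonian cell
    arrivals, lognormal per-cell masses, dwell binning, coincidence,
    fixation-leaching and debris effects) provides ground truth so every
    pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
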