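# scicpms

Signal processing and per-cell quantification for time-resolved
**single-cell ICP-MS** (SC-ICP-MS).

When a dilute cell suspension is aspirated into an ICP-MS running in
time-resolved mode, most dwell windows record only the dissolved matrix
background; a window that catches a cell records a transient count spike
carrying that one cell's entire content of the measured element. Reducing
such traces to biology — per-cell element masses and their population
distributions, e.g. Mg, Ca, Zn and Mn in macrophages during mycobacterial
infection — takes a chain of small, easy-to-get-wrong steps. This package
implements that chain for analysts working with mammalian cell suspensions
(and anyone doing single-particle ICP-MS on comparable data):

* **Event detection** — the iterative Poisson-statistics threshold: dwells
  above `mean + k·SD` of the current background set are removed and the
  loop repeats until nothing changes (k = 3 by default); maximal
  above-threshold runs become events with background-subtracted net counts.
* **Transport efficiency (TE)** — the fraction of aspirated cells that
  reach the plasma, by the pulse-frequency method
  `TE = N_peaks / (C_cell · Q · t_acq)` (with a model-based correction for
  the ~0.15%/dwell of pure background that a 3σ threshold inevitably
  flags), and by the particle-size method from matched dissolved/particle
  sensitivities.
* **Quantification** — dissolved-standard calibration with
  internal-standard drift correction, the per-cell mass unit chain
  `m = N_net · Q · t_dwell · TE / S` (reported in fg), and 3σ limits of
  detection both dissolved (ng/L) and per event (fg).
* **Population analysis** — kernel probability densities of per-cell mass
  with explicit below-LOD bookkeeping, heterogeneity summaries (CV, IQR,
  quantiles), bootstrap population comparisons, and the sample-preparation
  QC metrics (peak-count reduction, cell recovery against a 70% criterion,
  count stability within one baseline SD).
* **A synthetic acquisition generator** — Poissonian cell arrivals,
  lognormal per-cell masses, dwell binning, coincidence, fixation leaching
  and debris, fully seed-deterministic with ground truth, so every stage of
  the chain is testable without an instrument.

Everything is tidyverse-native: functions take data frames (traces, event
tables, standards, mass samples) first and return tibbles, fitted objects
have `tidy()`/`glance()` methods, and result types have `autoplot()`
methods.

## Worked example

Simulate one 60-s acquisition at typical operating conditions (5×10⁵
cells/mL, 0.3 mL/min, 3 ms dwell, true TE 0.1%, lognormal cell masses with
median 25 fg), then run the full reduction:

```r
library(scicpms)

sim   <- simulate_trace(sim_config(seed = 42))
trace <- sim$trace

bg <- iterative_threshold(trace, k_sigma = 3)
bg
#> <background_model> mean 2474, SD 49.74, threshold 2623 (k = 3),
#>   19806/20000 background dwells, 3 iteration(s)

events <- extract_events(trace, bg)
te <- te_pulse_frequency(events, 5e5)
te[, c("te_pct", "n_peaks", "n_peaks_detected", "expected_false_peaks")]
#>      te_pct n_peaks n_peaks_detected expected_false_peaks
#> 1 0.1087753 163.163              192              28.8371

slope  <- matched_calibration_slope(20, 0.001, 0.3, 0.003)  # counts/(ng/L)/dwell
masses <- quantify_events(events, slope, te)
heterogeneity_summary(masses)
#>   n_cells n_below_lod frac_below_lod median_fg mean_fg sd_fg    cv iqr_fg
#> 1     192           0              0      24.0    27.2  17.0 0.627   19.2
```

Reading the numbers: the threshold converged in 3 iterations to a cutoff of
2623 counts over a 2474-count background; 192 windows exceeded it, of which
~29 are the expected false positives of a 3σ cutoff over 20,000 background
windows, leaving 163 cell peaks and a TE estimate of 0.109% against the
simulated truth of 0.1%. Quantification recovers a right-skewed mass
distribution with median 24 fg (truth: 25 fg) and none of the detected
cells below the 8.1 fg event-mass LOD. `autoplot(trace, background = bg)`,
`autoplot(probability_density(masses))` and `plot_population_densities()`
draw the corresponding figures, and `compare_populations()` contrasts two
mass samples (e.g. infected vs uninfected cells) with bootstrap intervals.

`run_pipeline()` chains the same stages from a single YAML/list config and
writes `trace.csv`, `events.csv`, `masses.csv`, `report.json` and a run
manifest, byte-reproducibly for a fixed seed.

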