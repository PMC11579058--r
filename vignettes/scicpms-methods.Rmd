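---
title: "Signal processing for single-cell ICP-MS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal processing for single-cell ICP-MS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scicpms)
library(dplyr)
```

## The measurement this package models

In time-resolved single-cell ICP-MS (SC-ICP-MS), a dilute cell suspension is
aspirated into the plasma and the detector integrates ion counts into short,
fixed dwell windows (a few milliseconds each). Most windows see only the
dissolved background of the suspension; when a cell enters the plasma, its
entire elemental content ionises within a fraction of a millisecond and the
window containing it records a transient spike. Three quantities turn these
spikes into biology:

1. a **detection threshold** separating spikes from background,
2. the **transport efficiency** (TE) — the fraction of aspirated cells that
   actually reach the plasma and register as spikes, typically around 0.1%
   for a pneumatic nebuliser, and
3. a **dissolved calibration** that converts net spike counts into analyte
   mass, in femtograms per cell.

The package implements each stage as a plain function over tabular data,
plus a synthetic acquisition generator with complete ground truth so that
the whole chain can be validated end to end without instrument data.

## Event detection: the iterative mean + kSD threshold

`iterative_threshold()` starts from the full trace and repeatedly removes
every dwell whose counts exceed `mean + k_sigma * SD` of the current
background set, until a pass removes nothing (k = 3 by default, the field
convention). Convergence is guaranteed because the background set shrinks
monotonically; a 1000-iteration cap guards corrupt input and hitting it is
an error, never a silent stop.

Two decisions here deserve explanation:

* **Strict inequality.** Points strictly *greater than* the threshold are
  removed. With the non-strict convention a perfectly constant trace
  (empirical SD = 0) would flag every dwell as an event; with integer counts
  and any real noise the two conventions are indistinguishable.
* **The SD estimator.** By default the background SD is taken as
  `sqrt(mean)` — the Poisson counting-statistics value, which is what makes
  this a *Poisson statistics* algorithm. The alternative empirical sample SD
  (n − 1) is available via `sd_estimator = "sample"`. The Poisson form is
  the package default because it is robust on short traces: a couple of
  intense cell spikes among tens of dwells inflate an empirical SD so much
  that the first pass removes nothing and the loop converges immediately
  with the spikes still inside the "background". With `SD = sqrt(mean)` the
  canonical ten-dwell example — `[10, 12, 11, 9, 10, 500, 11, 10, 490, 12]`
  — removes the two spikes in two passes and converges to a background mean
  of 10.625. On long traces with rare spikes the two estimators agree
  closely, since the fitted background is Poisson to good approximation.

`extract_events()` then groups maximal runs of above-threshold dwells into
events, optionally bridging up to `merge_gap` below-threshold dwells inside
a run (default 0: at a 3-ms dwell a ~0.5-ms cell transient almost always
falls in one window). Net counts are the raw sum minus the expected
background over the spanned dwells, clipped at zero and flagged when
clipping occurred — a negative net count is a noise fluctuation, not a
negative mass.

### False positives are a property of the threshold, not a bug

A k = 3 threshold leaves a one-tailed background exceedance of roughly
0.14–0.3% per dwell (the exact value depends on the Poisson skew and where
the threshold falls between integers). On a 60-s acquisition at 3 ms —
20,000 dwells — that is on the order of **30 spurious peaks**, which matters
when the true cell count is only ~150. The converged `background_model`
therefore carries its own per-dwell exceedance probability
`P(counts > threshold)` under the fitted background, and
`expected_false_events()` scales it to the acquisition. The pulse-frequency
TE estimator subtracts this expected count by default (the raw detected
count is always reported alongside); without the correction the TE estimate
at the default study conditions is biased high by ~20%. This is a
model-based debiasing, not a tuned constant: it is computed from the same
Poisson assumption the detector itself uses.

## Transport efficiency

`te_pulse_frequency()` implements the standard pulse-frequency estimator

$$TE = \frac{N_{peaks}}{C_{cell} \; Q \; t_{acq}}$$

with the cell concentration from hemocytometry (cells/mL), the sample flow
Q (mL/min) and the acquisition time in minutes. When the suspension record
carries a Trypan-blue viability fraction, the intact-cell concentration is
used, because only intact cells produce spikes. Uncertainty is Poisson on
the detected peak count, with the hemocytometer replicate SD propagated in
quadrature when replicates are supplied (hemocytometer precision is
typically better than 10%).

`te_particle_size()` implements the complementary estimator: the dissolved
calibration slope S (counts per (ng/L) per dwell) corresponds to
`S / (Q t_{dwell})` counts per ng of *aspirated* analyte, and the ratio of
that to the observed response per fg of reference-particle mass is TE. The
two estimators close algebraically: `matched_calibration_slope()` converts a
detector sensitivity (counts/fg) into the dissolved slope it implies, and
`te_particle_size()` applied to that pair returns the TE used in the
conversion exactly.

`te_vs_concentration()` runs the pulse-frequency estimator along a
concentration series and flags the coincidence signature: above roughly
10^6 cells/mL several cells begin to share dwell windows, merged spikes
depress the apparent TE and inflate apparent masses. A point is flagged
when its estimate falls more than 3 combined SE below the
inverse-variance-weighted mean of all lower-concentration points.

## Quantification and limits of detection

`fit_calibration()` is ordinary least squares of response versus standard
concentration. When internal-standard counts are given (e.g. In at a fixed
added concentration), analyte counts are divided by
`is_counts / mean(is_counts)` first — a relative drift correction that
exactly cancels multiplicative drift common to both channels and is a no-op
when the IS response is constant. The fitted intercept is retained and
reported rather than forcing the line through the origin, keeping r²
honest.

`mass_per_event()` applies the unit chain

$$m_{cell} \,[\mathrm{fg}] = \frac{N_{net} \; Q_{L/s} \; t_{dwell} \; TE}{S} \times 10^{6},$$

with every conversion (mL/min to L/s, ng to fg) centralised in audited
helpers — unit drift being the classic failure mode of SP-ICP-MS
implementations. Worked anchor: 1000 net counts at S = 0.5, Q = 0.3 mL/min,
t = 3 ms, TE = 0.001 is 0.03 fg.

Two limits of detection are computed with the 3σ convention (the k is
exposed for labs preferring 3.29 or 10):

* `dissolved_lod()`: `3 SD(blank) / S`, in ng/L;
* `event_mass_lod()`: the mass equivalent of a net signal of
  `k_sigma × SD(background)` — the smallest single-cell mass the threshold
  can distinguish. Events below it are flagged, never imputed, and the
  below-LOD fraction is always reported (for elements like Mn most cells
  can sit below this floor, in which case a density curve is not
  meaningful).

`bulk_mass_per_cell()` and `bulk_vs_sc_relative_error()` support the bulk
comparison: a digest of a counted cell pellet includes cellular debris and
leached analyte as well as intact cells, so bulk mass-per-cell
systematically exceeds the single-cell mean, with large positive relative
errors in debris-laden suspensions.

## Population heterogeneity

`probability_density()` computes a Gaussian-kernel density of the above-LOD
masses on a grid from 0 to 1.1× the largest mass, with Silverman's rule as
the default bandwidth. Two normalisations are supported: `area_one`
(canonical; trapezoid integral over the grid is renormalised to exactly 1)
and `max_one` (peak at 1, convenient for overlaying populations whose cell
counts differ). `heterogeneity_summary()` reports location, spread (SD, CV,
IQR, 5th/95th percentiles) and the below-LOD fraction; "tight regulation"
reads as low CV and narrow IQR, and is reported rather than asserted.
`compare_populations()` gives the two-sample Kolmogorov–Smirnov statistic
plus seeded bootstrap percentile intervals on the median difference and the
CV ratio — a deliberately assumption-light toolkit, since no named test is
standard for these right-skewed, detection-truncated distributions.

## The synthetic acquisition generator

`simulate_trace()` is the forward model the analysis assumes, with full
ground truth:

* cell arrivals are a Poisson process at rate `C × Q × TE_true`;
* per-cell masses are lognormal (single-cell content distributions are
  right-skewed and unimodal), scaled by a fixation-retention fraction —
  imperfect fixation leaches analyte and moves cells below the detection
  floor, which is how leaching is read out as a drop in peak counts;
* each cell deposits `mass × sensitivity` expected counts over
  `ceiling(transient_width / dwell)` windows (default sub-dwell, so
  single-window events dominate at 3 ms);
* the matrix adds Poisson background per dwell; optional "debris" adds
  frequent low-amplitude exponential spikes that raise the background
  without creating events;
* observed counts are Poisson draws around the expected totals (detector
  shot noise), or exact rounding under `noiseless = TRUE` for round-trip
  tests.

Everything is a pure function of the `sim_config()`, including its
mandatory seed.

Default parameter choices, made once:

| parameter | default | why |
|---|---|---|
| cell concentration | 5×10^5 /mL | the optimum between event yield and coincidence |
| flow | 0.3 mL/min | the high-TE end of the usual 0.3–1.7 mL/min range |
| TE | 0.001 | what PFA-fixed THP-1 suspensions actually show (~0.1%) |
| dwell | 3 ms | shortest common integration time; the single-cell optimum |
| duration | 60 s | a standard single acquisition |
| background λ | 2474 counts/dwell | measured Mg background of a fixed THP-1 suspension in water (debris-dominated; the water blank alone is ~14) |
| sensitivity | 20 counts/fg | puts a median cell ~10 background SD above baseline |
| mass distribution | lognormal, median 25 fg, σ = 0.5 | plausible endogenous Mg per THP-1 cell; the true distribution is not tabulated anywhere, so this is a modelling choice, not a measured constant |
| transient width | 0.5 ms | sub-dwell ion cloud |

The experiment drivers reproduce the qualitative instrument-optimisation
trade-offs: `rebin_trace()`/`dwell_time_experiment()` show apparent TE
falling and maximum window counts rising essentially linearly as the
integration window widens (at 50–100 ms windows the threshold rises with
the accumulated background until single cells are no longer
distinguishable); `concentration_experiment()` shows event counts
proportional to concentration in the dilute regime, then saturating with
inflated apparent masses at ≥10^6 cells/mL; `fixation_experiment()` shows
peak-count reductions growing monotonically as the retained fraction falls,
when the mass distribution straddles the detection limit. The fixation
driver uses a paired design — the same seed, hence the same arrivals and
pre-leaching masses, across conditions — so condition differences are not
confounded with arrival noise.

### What the generator does and does not emulate

It captures the statistical structure the pipeline relies on: Poissonian
arrivals and counting noise, dwell binning, coincidence, a detection floor,
and background inflation by debris. It does not model plasma physics
(ionisation efficiency and aerosol transport are lumped into two
constants), correlated background drift, double-counted split transients at
sub-millisecond dwells, isotope interferences, or cell aggregates. Passing
tests therefore demonstrate the *data reduction* is correct under the
stated statistical assumptions — not that those assumptions exhaust real
acquisitions.

## Numerical choices and degenerate inputs

* Problem sizes in the test-suite simulations are one to twenty 60-s
  acquisitions (20,000 dwells each) per property, enough that Monte-Carlo
  error is far below every asserted margin.
* Density curves renormalise the trapezoid integral on the evaluation grid,
  so `area_one` holds to machine precision by construction; the 10^-3
  tolerance in tests guards the grid span.
* Silverman bandwidth degenerates to zero on constant samples; a fallback
  of 1% of the sample location keeps the curve finite.
* Traces must be integer counts; fractional counts in input files are an
  error (they indicate pre-processed data), never silently rounded.
* `iterative_threshold()` errors when fewer than two background dwells
  remain ("no background remains") and on traces shorter than 10 dwells.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  every simulation, bootstrap and pipeline run is reproducible bit for bit;
  `run_pipeline()` reports are byte-identical across runs of the same
  config, with only the manifest timestamp varying.

## Known limitations

* The pulse-frequency TE correction subtracts the *expected* false-peak
  count; the realised count fluctuates (Poisson), so single-acquisition TE
  estimates retain that noise floor.
* Below-LOD cells are excluded, not imputed; summary statistics are
  therefore conditional on detection, and comparisons between populations
  with very different below-LOD fractions should lean on the reported
  fractions, not only on the density curves.
* The bulk comparison quantifies the debris mechanism only qualitatively;
  real digests add matrix effects the package does not model.
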