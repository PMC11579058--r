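test_that("calibration on exact points recovers the line exactly", {
  std <- tibble::tibble(conc_ng_L = c(0, 100, 200), counts = c(0, 50, 100))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 0.5)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  expect_false(cal$is_corrected)

  # constant internal-standard counts: correction is a no-op
  std$is_counts <- rep(1000, 3)
  cal_is <- fit_calibration(std)
  expect_true(cal_is$is_corrected)
  expect_equal(cal_is$slope, 0.5)
})

test_that("IS correction removes multiplicative drift common to both channels", {
  withr::local_seed(8)
  conc <- c(0, 50, 100, 500, 1000, 2000)
  drift <- exp(rnorm(6, 0, 0.05))
  drift <- drift / mean(drift) # drift relative to the run average
  std <- tibble::tibble(conc_ng_L = conc,
                        counts = 0.5 * conc * drift,
                        is_counts = 1000 * drift)
  corrected <- fit_calibration(std)
  uncorrected <- fit_calibration(std[, c("conc_ng_L", "counts")])
  expect_equal(corrected$slope, 0.5, tolerance = 1e-12)
  expect_equal(corrected$intercept, 0, tolerance = 1e-9)
  expect_gt(abs(uncorrected$slope - 0.5), 1e-4)
})

test_that("calibration input contracts are enforced", {
  expect_error(fit_calibration(tibble::tibble(conc_ng_L = c(0, 1),
                                              counts = c(0, 1))),
               "at least 3")
  expect_error(fit_calibration(tibble::tibble(conc_ng_L = c(0, 1, 2),
                                              counts = c(0, 1, 2),
                                              is_counts = c(10, 0, 10))),
               "positive")
})

test_that("mass per event follows the documented unit chain", {
  # 1000 counts x 5e-6 L/s x 0.003 s x 0.001 / 0.5 = 3e-8 ng = 0.03 fg
  expect_equal(mass_per_event(1000, 0.5, 0.001, 0.3, 0.003), 0.03)
  expect_equal(mass_per_event(0, 0.5, 0.001, 0.3, 0.003), 0)
  expect_error(mass_per_event(10, 0.5, 0, 0.3, 0.003), "transport efficiency")
  expect_error(mass_per_event(10, -1, 0.001, 0.3, 0.003), "slope")
})

test_that("mass per event is exactly linear in each factor", {
  m <- mass_per_event(1000, 0.5, 0.001, 0.3, 0.003)
  expect_equal(mass_per_event(2000, 0.5, 0.001, 0.3, 0.003), 2 * m)
  expect_equal(mass_per_event(1000, 1.0, 0.001, 0.3, 0.003), m / 2)
  expect_equal(mass_per_event(1000, 0.5, 0.002, 0.3, 0.003), 2 * m)
  expect_equal(mass_per_event(1000, 0.5, 0.001, 0.6, 0.003), 2 * m)
  expect_equal(mass_per_event(1000, 0.5, 0.001, 0.3, 0.006), 2 * m)
})

test_that("noiseless fixed-mass cells quantify back to their true mass", {
  cfg <- study_config(seed = 21, mass_log_median_fg = 50, mass_log_sigma = 0,
                      noiseless = TRUE, duration_s = 40)
  sim <- simulate_trace(cfg)
  ev <- extract_events(sim$trace, iterative_threshold(sim$trace))
  slope <- matched_calibration_slope(cfg$sensitivity_counts_per_fg,
                                     cfg$te_true, cfg$flow_mL_min,
                                     cfg$dwell_time_s)
  masses <- mass_per_event(ev$net_counts, slope, cfg$te_true,
                           cfg$flow_mL_min, cfg$dwell_time_s)
  # each detected event carries 50 fg per true cell in its dwell span
  occupancy <- tabulate(sim$truth$start_dwell, nbins = n_dwells(sim$trace))
  cells_per_event <- mapply(function(s, n) sum(occupancy[s:(s + n - 1)]),
                            ev$start_index, ev$n_dwells)
  expect_true(all(cells_per_event >= 1))
  expect_equal(masses, 50 * cells_per_event, tolerance = 0.01)
})

test_that("dissolved LOD follows the 3-sigma blank convention", {
  expect_equal(dissolved_lod(c(7, 10, 13), 10), 3 * 3 / 10)
  expect_equal(dissolved_lod(rep(5, 4), 10), 0)
  blanks <- c(4, 8, 9, 12)
  expect_equal(dissolved_lod(blanks * 3, 10), 3 * dissolved_lod(blanks, 10))
  expect_equal(dissolved_lod(blanks, 10, k = 3.29),
               dissolved_lod(blanks, 10) * 3.29 / 3)
  expect_error(dissolved_lod(c(1, 2), 10), "3 blank")
  expect_error(dissolved_lod(c(1, 2, 3), 0), "positive")
})

test_that("event mass LOD maps the detection floor into femtograms", {
  bg0 <- structure(list(mean_counts = 10, sd_counts = 0, threshold_counts = 10,
                        k_sigma = 3, n_iterations = 1L,
                        background_indices = 1:10,
                        false_positive_rate = 0, n_dwells = 10L),
                   class = "background_model")
  expect_equal(event_mass_lod(bg0, 0.5, 0.001, 0.3, 0.003), 0)

  bg10 <- bg0
  bg10$sd_counts <- 10
  # 30 net counts at the worked unit chain -> 9e-4 fg
  expect_equal(event_mass_lod(bg10, 0.5, 0.001, 0.3, 0.003), 9e-4)
  # monotone in the background SD
  bg20 <- bg0
  bg20$sd_counts <- 20
  expect_gt(event_mass_lod(bg20, 0.5, 0.001, 0.3, 0.003),
            event_mass_lod(bg10, 0.5, 0.001, 0.3, 0.003))
})

test_that("below-LOD fraction tracks a population straddling the threshold", {
  cfg <- study_config(seed = 77, mass_log_median_fg = 8, mass_log_sigma = 0.6,
                      duration_s = 120, cells_per_mL = 2e6)
  sim <- simulate_trace(cfg)
  bg <- iterative_threshold(sim$trace)
  ev <- extract_events(sim$trace, bg)
  slope <- matched_calibration_slope(cfg$sensitivity_counts_per_fg,
                                     cfg$te_true, cfg$flow_mL_min,
                                     cfg$dwell_time_s)
  qm <- quantify_events(ev, slope, cfg$te_true)
  lod_fg <- attr(qm, "mass_lod_fg")
  truth_below <- mean(sim$truth$mass_fg < lod_fg)
  # population below-LOD fraction: cells the detector never saw plus
  # detected-but-below-LOD events; spurious background peaks (which sit
  # marginally above the LOD) are removed in expectation
  n_above <- sum(!qm$below_lod) - expected_false_events(bg)
  est_below <- 1 - n_above / nrow(sim$truth)
  expect_lt(abs(est_below - truth_below), 0.05)
})

test_that("bulk digests convert to mass per cell and compare to single cell", {
  expect_equal(bulk_mass_per_cell(100, 0.01, 10, 1e7), 1)
  expect_equal(bulk_mass_per_cell(0, 0.01, 10, 1e7), 0)
  expect_equal(bulk_mass_per_cell(100, 0.01, 20, 1e7),
               2 * bulk_mass_per_cell(100, 0.01, 10, 1e7))
  expect_error(bulk_mass_per_cell(100, 0.01, 10, 0), "positive")

  expect_equal(bulk_vs_sc_relative_error(10, 1), 90)
  expect_equal(bulk_vs_sc_relative_error(10, 10), 0)
  expect_error(bulk_vs_sc_relative_error(0, 1), "positive")
})

test_that("debris in the digest inflates bulk mass per cell above the single-cell mean", {
  withr::local_seed(3)
  n_cells <- 1e6
  cell_masses_fg <- rlnorm(5000, log(25), 0.5)
  sc_mean <- mean(cell_masses_fg)
  # sub-cellular debris contributes analyte to the digest but produces no
  # single-cell peaks; here it carries 4x the intact-cell analyte pool
  total_fg <- mean(cell_masses_fg) * n_cells * 5
  digest_L <- 0.01
  conc_ng_L <- (total_fg / 1e6) / digest_L
  bulk <- bulk_mass_per_cell(conc_ng_L, digest_L, 1, n_cells)
  err <- bulk_vs_sc_relative_error(bulk, sc_mean)
  expect_gt(err, 0)
  expect_equal(err, 80)
})

test_that("matched_calibration_slope inverts mass_per_event", {
  slope <- matched_calibration_slope(20, 0.001, 0.3, 0.003)
  # a 1 fg cell produces 20 counts; quantifying 20 counts returns 1 fg
  expect_equal(mass_per_event(20, slope, 0.001, 0.3, 0.003), 1)
})
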