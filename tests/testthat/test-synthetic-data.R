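test_that("sim_config validates its fields and requires a seed", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, te_true = 1.5), "te_true")
  expect_error(sim_config(seed = 1, leach_retained_fraction = -0.1), "leach")
  cfg <- sim_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
  cfg2 <- update_config(cfg, cells_per_mL = 1e4)
  expect_equal(cfg2$cells_per_mL, 1e4)
  expect_equal(cfg2$seed, 1L)
})

test_that("identical configs give bit-identical traces and truth", {
  cfg <- sim_config(seed = 123, duration_s = 10)
  s1 <- simulate_trace(cfg)
  s2 <- simulate_trace(cfg)
  expect_identical(s1$trace$counts, s2$trace$counts)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- simulate_trace(update_config(cfg, seed = 124))
  expect_false(identical(s1$trace$counts, s3$trace$counts))
})

test_that("a cell-free trace is pure Poisson background at the set level", {
  cfg <- sim_config(seed = 55, cells_per_mL = 0, background_lambda = 10,
                    duration_s = 30) # 1e4 dwells
  sim <- simulate_trace(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(n_dwells(sim$trace), 1e4)
  se <- sqrt(10 / 1e4)
  expect_lt(abs(mean(sim$trace$counts) - 10), 3 * se)
})

test_that("event counts follow the aspirated-cell Poisson mean", {
  counts <- vapply(1:20, function(s) {
    nrow(simulate_trace(sim_config(seed = 400 + s))$truth)
  }, numeric(1))
  # C x Q x TE x t = 5e5 x 0.005 mL/s x 0.001 x 60 s = 150
  expect_lt(abs(mean(counts) - 150), 3 * sqrt(150) / sqrt(20))
})

test_that("truth event counts are Poisson-dispersed across seeds", {
  counts <- vapply(1:400, function(s) {
    nrow(simulate_trace(sim_config(seed = 500 + s, duration_s = 10))$truth)
  }, numeric(1))
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("the noiseless forward model is exactly invertible per dwell", {
  cfg <- sim_config(seed = 66, background_lambda = 0, noiseless = TRUE,
                    duration_s = 30)
  sim <- simulate_trace(cfg)
  occ <- tabulate(sim$truth$start_dwell, nbins = n_dwells(sim$trace))
  single <- sim$truth$start_dwell[occ[sim$truth$start_dwell] == 1]
  masses <- sim$truth$mass_fg[occ[sim$truth$start_dwell] == 1]
  expect_gt(length(single), 0)
  expect_identical(sim$trace$counts[single],
                   as.integer(round(masses * cfg$sensitivity_counts_per_fg)))
})

test_that("detect->quantify recovers each mass to under 1% without noise", {
  cfg <- sim_config(seed = 67, background_lambda = 0, noiseless = TRUE,
                    duration_s = 30)
  sim <- simulate_trace(cfg)
  ev <- extract_events(sim$trace, iterative_threshold(sim$trace))
  slope <- matched_calibration_slope(cfg$sensitivity_counts_per_fg,
                                     cfg$te_true, cfg$flow_mL_min,
                                     cfg$dwell_time_s)
  got <- mass_per_event(ev$net_counts, slope, cfg$te_true, cfg$flow_mL_min,
                        cfg$dwell_time_s)
  true_per_event <- mapply(function(s, n) {
    sum(sim$truth$mass_fg[sim$truth$start_dwell %in% s:(s + n - 1)])
  }, ev$start_index, ev$n_dwells)
  expect_equal(got, unname(true_per_event), tolerance = 0.01)
})

test_that("the heavy-coincidence regime is flagged in the truth record", {
  cfg <- sim_config(seed = 3, cells_per_mL = 5e8, duration_s = 2)
  sim <- suppressWarnings(simulate_trace(cfg))
  expect_match(attr(sim$truth, "warnings"), "coincidence")
  quiet <- simulate_trace(sim_config(seed = 3, duration_s = 2))
  expect_length(attr(quiet$truth, "warnings"), 0)
})

test_that("rebinning sums blocks, scales the dwell and conserves counts", {
  tr <- icp_trace(c(1, 2, 3, 4), 0.003)
  expect_identical(rebin_trace(tr, 1), tr)
  r2 <- rebin_trace(tr, 2)
  expect_equal(r2$counts, c(3L, 7L))
  expect_equal(dwell_time(r2), 0.006)
  expect_error(rebin_trace(tr, 0), "integer")

  withr::local_seed(14)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    f <- sample(2:7, 1)
    tr <- icp_trace(rpois(n, 30), 0.003)
    if (n %% f != 0) expect_warning(rebin_trace(tr, f), "trailing")
    r <- suppressWarnings(rebin_trace(tr, f))
    kept <- (n %/% f) * f
    expect_equal(sum(r$counts), sum(tr$counts[seq_len(kept)]))
    expect_equal(acquisition_duration(r), kept * 0.003)
  }
})

test_that("wider integration windows trade efficiency for peak height", {
  res <- dwell_time_experiment(sim_config(seed = 71), c(1, 2, 4, 8, 16, 32))
  expect_equal(nrow(res), 6L)
  # per-seed: maximum is non-decreasing by construction (sums of counts)
  expect_true(all(diff(res$max_intensity) >= 0))
  expect_true(all(diff(res$te_est) <= 0))
  single <- dwell_time_experiment(sim_config(seed = 71), 4)
  expect_equal(nrow(single), 1L)
  expect_equal(single$dwell_s, 0.012)
})

test_that("the concentration series saturates and inflates mass at the top end", {
  res <- concentration_experiment(sim_config(seed = 81),
                                  c(1e5, 5e5, 5e6))
  expect_equal(nrow(res), 3L)
  # corrected counts roughly proportional in the dilute pair
  ratio <- res$n_events_corrected[2] / res$n_events_corrected[1]
  expect_lt(abs(ratio - 5), 3 * ratio * sqrt(1 / 30 + 1 / 150))
  # coincidence: apparent TE down, apparent median mass up at 5e6 cells/mL
  expect_lt(res$te_est[3], res$te_est[2])
  expect_gt(res$median_mass_fg[3], res$median_mass_fg[2])
  empty <- concentration_experiment(sim_config(seed = 81), numeric())
  expect_equal(nrow(empty), 0L)
})

test_that("fixation leaching reduces peaks monotonically when masses straddle the LOD", {
  base <- sim_config(seed = 91, mass_log_median_fg = 10, mass_log_sigma = 0.6)
  res <- fixation_experiment(base, c(pfa = 1, meoh_mild = 0.7, meoh_harsh = 0.3))
  expect_equal(res$reduction_pct[1], 0)
  expect_true(all(diff(res$reduction_pct) > 0))
  expect_gt(res$reduction_pct[3], 30)
  expect_error(fixation_experiment(base, c(a = 1, b = 1.4)), "\\[0, 1\\]")

  # no leaching difference, paired arrivals: reductions stay near zero
  null <- fixation_experiment(base, c(ref = 1, same = 1))
  expect_lt(abs(null$reduction_pct[2]), 15)
})
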