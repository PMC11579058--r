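worked_trace <- function() {
  icp_trace(c(10, 12, 11, 9, 10, 500, 11, 10, 490, 12), 0.003)
}

test_that("the ten-dwell worked trace converges to the known background", {
  bg <- iterative_threshold(worked_trace(), k_sigma = 3)
  expect_equal(bg$mean_counts, 10.625)
  expect_equal(bg$sd_counts, sqrt(10.625))
  expect_equal(bg$threshold_counts, 10.625 + 3 * sqrt(10.625))
  expect_equal(bg$n_iterations, 2L)
  expect_identical(bg$background_indices, setdiff(1:10, c(6L, 9L)))

  ev <- extract_events(worked_trace(), bg)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_index, c(6L, 9L))
  expect_equal(ev$net_counts, c(500, 490) - 10.625)
})

test_that("a constant trace flags nothing under the empirical-SD variant", {
  tr <- icp_trace(rep(5L, 12), 0.003)
  bg <- iterative_threshold(tr, k_sigma = 3, sd_estimator = "sample")
  expect_equal(bg$mean_counts, 5)
  expect_equal(bg$sd_counts, 0)
  expect_equal(bg$threshold_counts, 5)
  expect_equal(bg$n_iterations, 1L)
  expect_length(bg$background_indices, 12L)
  expect_equal(bg$false_positive_rate, 0)
})

test_that("iterative threshold matches the brute-force oracle exactly", {
  withr::local_seed(42)
  for (i in 1:300) {
    est <- if (i %% 2 == 0) "poisson" else "sample"
    tr <- make_spiky_trace(n = sample(50:500, 1),
                           lambda = runif(1, 1, 200),
                           n_spikes = sample(0:10, 1))
    got <- iterative_threshold(tr, k_sigma = 3, sd_estimator = est)
    want <- brute_force_threshold(as.numeric(tr$counts), 3, est)
    expect_identical(got$background_indices, as.integer(want$background_indices))
    expect_equal(got$mean_counts, want$mean)
    expect_equal(got$sd_counts, want$sd)
    expect_equal(got$n_iterations, as.integer(want$iterations))
  }
})

test_that("pure Poisson background is rarely flagged", {
  fractions <- vapply(1:20, function(s) {
    tr <- withr::with_seed(s, icp_trace(rpois(6e4, 100), 0.003))
    bg <- iterative_threshold(tr)
    1 - length(bg$background_indices) / 6e4
  }, numeric(1))
  expect_lt(mean(fractions), 0.005)
  # and the model's own false-positive rate predicts the flagged fraction
  expect_equal(mean(fractions),
               ppois(floor(100 + 3 * 10), 100, lower.tail = FALSE),
               tolerance = 0.15)
})

test_that("pathological traces error instead of converging to nothing", {
  # geometric counts: each pass strips the top until too few remain
  tr <- icp_trace(2L^(0:11), 0.003)
  expect_error(iterative_threshold(tr, k_sigma = 0.1), "no background remains")
  expect_error(iterative_threshold(icp_trace(rep(1L, 5), 0.003)), "at least 10")
  expect_error(iterative_threshold(worked_trace(), k_sigma = -1), "k_sigma")
})

test_that("event extraction integrates runs and subtracts background", {
  counts <- c(rep(10L, 10), 500L, rep(10L, 5))
  tr <- icp_trace(counts, 0.003)
  bg <- iterative_threshold(tr)
  ev <- extract_events(tr, bg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_dwells, 1L)
  expect_equal(ev$net_counts, 500 - bg$mean_counts)
  expect_equal(ev$start_time_s, 10 * 0.003)

  # adjacent above-threshold dwells form one event even at merge_gap = 0
  counts2 <- c(rep(10L, 10), 400L, 420L, rep(10L, 5))
  tr2 <- icp_trace(counts2, 0.003)
  ev2 <- extract_events(tr2, iterative_threshold(tr2), merge_gap = 0)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$n_dwells, 2L)

  # one below-threshold dwell inside a run is bridged at merge_gap = 1
  counts3 <- c(rep(10L, 10), 400L, 10L, 420L, rep(10L, 5))
  tr3 <- icp_trace(counts3, 0.003)
  bg3 <- iterative_threshold(tr3)
  expect_equal(nrow(extract_events(tr3, bg3, merge_gap = 0)), 2L)
  ev3 <- extract_events(tr3, bg3, merge_gap = 1)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$n_dwells, 3L)
  expect_equal(ev3$raw_counts, 400 + 10 + 420)
})

test_that("a background model fitted elsewhere is rejected", {
  tr_a <- icp_trace(rpois(100, 10), 0.003)
  tr_b <- icp_trace(rpois(120, 10), 0.003)
  expect_error(extract_events(tr_b, iterative_threshold(tr_a)),
               "different length")
})

test_that("detection recovers simulated ground truth at high signal-to-background", {
  cfg <- study_config(seed = 7, background_lambda = 10,
                      sensitivity_counts_per_fg = 100, duration_s = 30)
  sim <- simulate_trace(cfg)
  ev <- extract_events(sim$trace, iterative_threshold(sim$trace), merge_gap = 1)
  # recall 1: every true event dwell lies inside a detected event
  spans <- unlist(mapply(function(s, n) s:(s + n - 1), ev$start_index,
                         ev$n_dwells, SIMPLIFY = FALSE))
  expect_true(all(sim$truth$start_dwell %in% spans))
  # no split events: no two detected events share one truth dwell span
  expect_equal(anyDuplicated(spans), 0L)
})

test_that("event count is non-increasing in the threshold multiplier", {
  withr::local_seed(13)
  for (i in 1:10) {
    tr <- make_spiky_trace(300, lambda = runif(1, 5, 100), n_spikes = 8)
    n_ev <- vapply(c(2, 3, 4, 5, 7),
                   function(k) nrow(extract_events(tr, iterative_threshold(tr, k))),
                   numeric(1))
    expect_true(all(diff(n_ev) <= 0))
  }
})

test_that("the threshold is idempotent on its own background set", {
  withr::local_seed(99)
  tr <- make_spiky_trace(400, lambda = 50, n_spikes = 6)
  bg <- iterative_threshold(tr)
  sub <- icp_trace(tr$counts[bg$background_indices], dwell_time(tr))
  bg2 <- iterative_threshold(sub)
  expect_equal(bg2$n_iterations, 1L)
  expect_length(bg2$background_indices, length(bg$background_indices))
  expect_equal(bg2$mean_counts, bg$mean_counts)
})

test_that("detection is deterministic", {
  tr <- withr::with_seed(5, make_spiky_trace(500, 80, 5))
  e1 <- extract_events(tr, iterative_threshold(tr))
  e2 <- extract_events(tr, iterative_threshold(tr))
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("max_intensity returns the per-dwell maximum", {
  expect_equal(max_intensity(icp_trace(c(1, 9, 3), 0.003)), 9L)
  expect_equal(max_intensity(icp_trace(rep(7L, 4), 0.003)), 7L)
})

test_that("event tables round-trip through CSV with their background header", {
  tr <- worked_trace()
  ev <- extract_events(tr, iterative_threshold(tr))
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p)
  back <- read_events(p)
  for (col in names(ev)) expect_equal(back[[col]], ev[[col]], label = col)
  expect_true(is.na(attr(back, "flow_mL_min")))
  expect_equal(attr(back, "background")$mean_counts, 10.625)
  expect_equal(attr(back, "background")$false_positive_rate,
               attr(ev, "background")$false_positive_rate)
  expect_equal(attr(back, "background")$k_sigma, 3)
  expect_equal(attr(back, "dwell_time_s"), 0.003)
})
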