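#' Configuration for the synthetic trace generator
#'
#' Bundles every knob of the forward model behind [simulate_trace()].
#' Defaults describe a typical fixed mammalian-cell acquisition: 5e5
#' cells/mL aspirated at 0.3 mL/min for 60 s at a 3-ms dwell with a
#' transport efficiency of 0.1%, a debris-laden matrix background of 2474
#' counts/dwell (what a fixed THP-1 suspension in deionised water shows for
#' Mg, far above the ~14-count water blank), and right-skewed (lognormal)
#' per-cell masses around 25 fg at a detector response of 20 counts/fg, so
#' a median cell is a ~500-count spike about ten background SDs above the
#' baseline.
#'
#' @param cells_per_mL Cell number concentration (hemocytometer scale).
#' @param flow_mL_min Sample uptake rate, mL/min.
#' @param te_true True transport efficiency fraction in `[0, 1]`.
#' @param dwell_time_s Dwell (integration) time, s.
#' @param duration_s Acquisition length, s.
#' @param background_lambda Mean matrix background, counts/dwell (Poisson).
#' @param sensitivity_counts_per_fg Detector response to cell mass,
#'   counts per fg (single lumped constant; no plasma physics).
#' @param mass_log_median_fg Median of the lognormal per-cell mass, fg.
#' @param mass_log_sigma Lognormal shape (sdlog).
#' @param transient_width_s Duration of one cell's ion cloud, s. The
#'   default 0.5 ms is sub-dwell at 3 ms, so single-dwell events dominate.
#' @param leach_retained_fraction Fraction of intracellular analyte retained
#'   after fixation (1 = no leaching); scales every cell's mass.
#' @param debris_rate_per_s Rate of sub-cellular debris spikes, per second.
#' @param debris_mean_counts Mean amplitude of a debris spike
#'   (exponential tail); keep below the detection threshold to emulate a
#'   raised background rather than false events.
#' @param noiseless If `TRUE`, per-dwell counts are `round(lambda + signal)`
#'   instead of Poisson draws — used for exact round-trip checks.
#' @param seed Integer seed; mandatory, the simulation is fully
#'   seed-deterministic.
#' @param element Isotope label carried onto the trace.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(cells_per_mL = 5e5,
                       flow_mL_min = 0.3,
                       te_true = 0.001,
                       dwell_time_s = 0.003,
                       duration_s = 60,
                       background_lambda = 2474,
                       sensitivity_counts_per_fg = 20,
                       mass_log_median_fg = 25,
                       mass_log_sigma = 0.5,
                       transient_width_s = 5e-4,
                       leach_retained_fraction = 1,
                       debris_rate_per_s = 0,
                       debris_mean_counts = 5,
                       noiseless = FALSE,
                       seed,
                       element = "24Mg") {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  cfg <- list(cells_per_mL = cells_per_mL, flow_mL_min = flow_mL_min,
              te_true = te_true, dwell_time_s = dwell_time_s,
              duration_s = duration_s, background_lambda = background_lambda,
              sensitivity_counts_per_fg = sensitivity_counts_per_fg,
              mass_log_median_fg = mass_log_median_fg,
              mass_log_sigma = mass_log_sigma,
              transient_width_s = transient_width_s,
              leach_retained_fraction = leach_retained_fraction,
              debris_rate_per_s = debris_rate_per_s,
              debris_mean_counts = debris_mean_counts,
              noiseless = isTRUE(noiseless),
              seed = as.integer(seed), element = element)
  with(cfg, {
    stopifnot(cells_per_mL >= 0, flow_mL_min > 0,
              te_true >= 0, te_true <= 1,
              dwell_time_s > 0, duration_s > 0,
              background_lambda >= 0, sensitivity_counts_per_fg >= 0,
              mass_log_median_fg >= 0, mass_log_sigma >= 0,
              transient_width_s > 0,
              leach_retained_fraction >= 0, leach_retained_fraction <= 1,
              debris_rate_per_s >= 0, debris_mean_counts >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' Modify a simulation configuration
#'
#' Returns a revalidated copy of `config` with the named fields replaced.
#'
#' @param config A [sim_config()].
#' @param ... Named fields to replace.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  args <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, args)
}

#' Simulate a dwell-resolved single-cell acquisition with ground truth
#'
#' Forward model of the acquisition the analysis chain assumes: cells
#' arrive as a Poisson process at rate `cells_per_mL x flow x te_true`;
#' each carries a lognormal mass scaled by the fixation-retention fraction;
#' a cell's ion cloud deposits `mass x sensitivity` expected counts spread
#' over `ceiling(transient_width / dwell)` dwell windows; the matrix adds a
#' Poisson background per dwell, and optional debris adds frequent
#' low-amplitude exponential spikes. Per-dwell counts are Poisson draws
#' around the expected total (shot noise), or deterministic rounding when
#' `noiseless = TRUE`. Everything is a pure function of the config,
#' including its seed.
#'
#' @param config A [sim_config()].
#' @return A list with `trace` (an [icp_trace()]) and `truth` (class
#'   `sim_truth`): tibble of true `event_time_s`, `mass_fg`, `start_dwell`,
#'   `coincident` (another true event in the same dwell), with attributes
#'   `config`, `expected_events` and `warnings` (e.g. the heavy-coincidence
#'   regime flag when expected events exceed half the dwell count).
#' @examples
#' sim <- simulate_trace(sim_config(seed = 1, duration_s = 5))
#' nrow(sim$truth)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_dw <- as.integer(round(config$duration_s / config$dwell_time_s))
  if (n_dw < 1) stop("acquisition shorter than one dwell", call. = FALSE)

  rate_per_s <- config$cells_per_mL *
    flow_mL_per_min_to_mL_per_s(config$flow_mL_min) * config$te_true
  expected <- rate_per_s * config$duration_s
  warnings <- character()
  if (expected > 0.5 * n_dw) {
    warnings <- c(warnings, "heavy coincidence regime: expected events exceed half the dwell count")
  }

  res <- withr::with_seed(config$seed, {
    n_ev <- stats::rpois(1, expected)
    times <- sort(stats::runif(n_ev, 0, config$duration_s))
    masses <- stats::rlnorm(n_ev, meanlog = log(config$mass_log_median_fg),
                            sdlog = config$mass_log_sigma) *
      config$leach_retained_fraction

    span <- max(1L, as.integer(ceiling(config$transient_width_s / config$dwell_time_s)))
    signal <- numeric(n_dw)
    start_dwell <- pmin(n_dw, floor(times / config$dwell_time_s) + 1L)
    if (n_ev > 0) {
      per_dwell <- masses * config$sensitivity_counts_per_fg / span
      at_all <- as.vector(outer(start_dwell, 0:(span - 1L), `+`))
      w_all <- rep(per_dwell, times = span)
      keep <- at_all <= n_dw
      # rowsum accumulates coincident contributions sharing one dwell
      acc <- rowsum(w_all[keep], group = at_all[keep])
      signal[as.integer(rownames(acc))] <- acc[, 1]
    }

    if (config$debris_rate_per_s > 0) {
      n_db <- stats::rpois(1, config$debris_rate_per_s * config$duration_s)
      if (n_db > 0) {
        db_at <- sample.int(n_dw, n_db, replace = TRUE)
        db_amp <- stats::rexp(n_db, rate = 1 / config$debris_mean_counts)
        for (i in seq_len(n_db)) signal[db_at[i]] <- signal[db_at[i]] + db_amp[i]
      }
    }

    mu <- config$background_lambda + signal
    counts <- if (config$noiseless) round(mu) else stats::rpois(n_dw, mu)
    list(counts = counts, times = times, masses = masses,
         start_dwell = start_dwell)
  })

  occupancy <- tabulate(res$start_dwell, nbins = n_dw)
  truth <- tibble::tibble(
    event_time_s = res$times,
    mass_fg = res$masses,
    start_dwell = as.integer(res$start_dwell),
    coincident = occupancy[res$start_dwell] > 1
  )
  truth <- structure(truth, class = c("sim_truth", class(truth)),
                     config = config, expected_events = expected,
                     warnings = warnings)
  trace <- icp_trace(res$counts, dwell_time_s = config$dwell_time_s,
                     element = config$element,
                     flow_mL_min = config$flow_mL_min)
  list(trace = trace, truth = truth)
}

#' Rebin a trace to a wider integration window
#'
#' Sums consecutive blocks of `factor` dwells, emulating acquisition at a
#' longer integration time. Total counts over the retained span are
#' conserved exactly; a trailing remainder that does not fill a block is
#' dropped with a warning.
#'
#' @param trace An [icp_trace()].
#' @param factor Integer >= 1; 1 is the identity.
#' @return An [icp_trace()] with `factor`-fold fewer dwells and
#'   `factor`-fold longer dwell time.
#' @examples
#' rebin_trace(icp_trace(c(1, 2, 3, 4), 0.003), 2)$counts # 3, 7
#' @export
rebin_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "icp_trace"))
  if (factor < 1 || factor != round(factor)) {
    stop("factor must be an integer >= 1", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(trace)
  n <- nrow(trace)
  n_blocks <- n %/% factor
  if (n_blocks == 0) stop("trace shorter than one block", call. = FALSE)
  if (n %% factor != 0) {
    warning(sprintf("dropping %d trailing dwell(s) not filling a block",
                    n %% factor), call. = FALSE)
  }
  kept <- trace$counts[seq_len(n_blocks * factor)]
  binned <- colSums(matrix(kept, nrow = factor))
  icp_trace(binned, dwell_time_s = dwell_time(trace) * factor,
            element = attr(trace, "element"),
            flow_mL_min = attr(trace, "flow_mL_min"),
            nebuliser_gas_L_min = attr(trace, "nebuliser_gas_L_min"))
}

#' Integration-time trade-off experiment
#'
#' Simulates one acquisition, rebins it to each integration-time factor,
#' and runs detection and pulse-frequency transport-efficiency estimation
#' at each width. Reproduces the dwell-time trade-off: wider windows merge
#' coincident cells (apparent TE falls) while the maximum per-window count
#' rises roughly linearly with the window.
#'
#' @param config A [sim_config()].
#' @param factors Sorted integer rebin factors (>= 1).
#' @param k_sigma Detection threshold multiplier.
#' @return A tibble with one row per factor: `factor`, `dwell_s`,
#'   `n_events`, `te_est`, `max_intensity`.
#' @export
dwell_time_experiment <- function(config, factors = c(1, 2, 4, 8, 16, 32),
                                  k_sigma = 3) {
  stopifnot(inherits(config, "sim_config"), all(factors >= 1),
            !is.unsorted(factors))
  sim <- simulate_trace(config)
  purrr::map_dfr(factors, function(f) {
    tr <- suppressWarnings(rebin_trace(sim$trace, f))
    ev <- extract_events(tr, iterative_threshold(tr, k_sigma = k_sigma))
    te <- te_pulse_frequency(ev, config$cells_per_mL,
                             flow_mL_min = config$flow_mL_min,
                             duration_s = acquisition_duration(tr))
    tibble::tibble(factor = as.integer(f), dwell_s = dwell_time(tr),
                   n_events = nrow(ev), te_est = te$te,
                   max_intensity = max_intensity(tr))
  })
}

#' Cell-concentration series experiment
#'
#' Simulates, detects and quantifies one acquisition per concentration with
#' the transport efficiency fixed at its true value and the calibration
#' slope matched to the simulated sensitivity, isolating the effect of
#' concentration itself. In the dilute regime the event count is
#' proportional to concentration; past the coincidence onset events merge,
#' the count saturates and the median apparent mass inflates.
#'
#' @param base A [sim_config()]; each point reuses it with the
#'   concentration replaced and a per-point child seed.
#' @param concentrations Ascending cell concentrations, cells/mL.
#' @param k_sigma Detection threshold multiplier.
#' @return A tibble with one row per concentration: `cells_per_mL`,
#'   `n_events` (detected), `n_events_corrected` (detected minus the
#'   expected false-positive count), `te_est`, `median_mass_fg`.
#' @export
concentration_experiment <- function(base, concentrations, k_sigma = 3) {
  stopifnot(inherits(base, "sim_config"))
  if (length(concentrations) == 0) {
    return(tibble::tibble(cells_per_mL = numeric(), n_events = integer(),
                          n_events_corrected = numeric(),
                          te_est = numeric(), median_mass_fg = numeric()))
  }
  stopifnot(!is.unsorted(concentrations))
  slope <- matched_calibration_slope(base$sensitivity_counts_per_fg,
                                     base$te_true, base$flow_mL_min,
                                     base$dwell_time_s)
  purrr::imap_dfr(concentrations, function(conc, i) {
    cfg <- update_config(base, cells_per_mL = conc,
                         seed = child_seed(base$seed, i))
    sim <- simulate_trace(cfg)
    bg <- iterative_threshold(sim$trace, k_sigma = k_sigma)
    ev <- extract_events(sim$trace, bg)
    te <- te_pulse_frequency(ev, conc, flow_mL_min = cfg$flow_mL_min,
                             duration_s = acquisition_duration(sim$trace))
    med <- if (nrow(ev) > 0) {
      stats::median(mass_per_event(ev$net_counts, slope, base$te_true,
                                   cfg$flow_mL_min, cfg$dwell_time_s))
    } else NA_real_
    tibble::tibble(cells_per_mL = conc, n_events = nrow(ev),
                   n_events_corrected = max(0, nrow(ev) - expected_false_events(bg)),
                   te_est = te$te, median_mass_fg = med)
  })
}

#' Fixation-leaching experiment
#'
#' Simulates one acquisition per fixation condition, varying only the
#' fraction of intracellular analyte retained, with identical cell arrivals
#' and pre-leaching masses across conditions (a paired design: the same
#' seed drives every condition). When the mass distribution straddles the
#' detection limit, leaching pushes cells below the threshold and the peak
#' count drops — the mechanism by which leaching is read out as a
#' percentage reduction in detected peaks relative to the reference
#' fixation.
#'
#' @param base A [sim_config()].
#' @param retained_fractions Named numeric vector of retention fractions in
#'   `[0, 1]`; the first entry is the reference condition.
#' @param k_sigma Detection threshold multiplier.
#' @return A tibble with one row per condition: `condition`,
#'   `retained_fraction`, `n_events`, `reduction_pct` (vs the first
#'   condition).
#' @export
fixation_experiment <- function(base, retained_fractions, k_sigma = 3) {
  stopifnot(inherits(base, "sim_config"), length(retained_fractions) >= 1)
  if (any(retained_fractions < 0 | retained_fractions > 1)) {
    stop("retained fractions must lie in [0, 1]", call. = FALSE)
  }
  nm <- names(retained_fractions) %||% paste0("condition_", seq_along(retained_fractions))
  res <- purrr::imap_dfr(as.numeric(retained_fractions), function(fr, i) {
    cfg <- update_config(base, leach_retained_fraction = fr)
    sim <- simulate_trace(cfg)
    ev <- extract_events(sim$trace, iterative_threshold(sim$trace, k_sigma = k_sigma))
    tibble::tibble(condition = nm[[i]], retained_fraction = fr,
                   n_events = nrow(ev))
  })
  res$reduction_pct <- peak_reduction_pct(res$n_events[1], res$n_events)
  res
}
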