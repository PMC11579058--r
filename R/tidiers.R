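#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a background model
#'
#' @param x A `background_model` from [iterative_threshold()].
#' @param ... Unused.
#' @return A one-row tibble with the background mean, SD, threshold,
#'   k multiplier, iteration count and background dwell count.
#' @exportS3Method generics::tidy
tidy.background_model <- function(x, ...) {
  tibble::tibble(
    mean_counts = x$mean_counts,
    sd_counts = x$sd_counts,
    threshold_counts = x$threshold_counts,
    k_sigma = x$k_sigma,
    n_iterations = x$n_iterations,
    n_background = length(x$background_indices),
    n_dwells = x$n_dwells
  )
}

#' Tidy / glance a calibration fit
#'
#' `tidy()` returns the coefficient-level view (slope and intercept with
#' standard errors from the underlying OLS fit); `glance()` returns the
#' one-row fit summary.
#'
#' @param x A `calibration_fit` from [fit_calibration()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "t value"]),
    p.value = unname(co[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.calibration_fit
#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    is_corrected = x$is_corrected,
    n_standards = nrow(x$standards),
    conc_min_ng_L = x$conc_range[1],
    conc_max_ng_L = x$conc_range[2]
  )
}

#' Tidy a population comparison
#'
#' One row per reported divergence statistic, with the bootstrap interval
#' bounds where applicable.
#'
#' @param x A `population_comparison` from [compare_populations()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.population_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = c("ks_statistic", "median_diff_fg", "cv_ratio"),
    estimate = c(x$ks_statistic, x$median_diff, x$cv_ratio),
    conf.low = c(NA, x$median_diff_ci[1], x$cv_ratio_ci[1]),
    conf.high = c(NA, x$median_diff_ci[2], x$cv_ratio_ci[2])
  )
}

#' @rdname tidy.population_comparison
#' @exportS3Method generics::glance
glance.population_comparison <- function(x, ...) {
  tibble::tibble(n_a = x$n_a, n_b = x$n_b, n_boot = x$n_boot,
                 seed = x$seed, conf_level = x$conf_level,
                 n_warnings = length(x$warnings))
}
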