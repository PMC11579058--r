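usable_masses <- function(sample, exclude_below_lod = TRUE) {
  stopifnot(is.data.frame(sample), "mass_fg" %in% names(sample))
  below <- if ("below_lod" %in% names(sample)) sample$below_lod else
    rep(FALSE, nrow(sample))
  below[is.na(below)] <- FALSE
  list(masses = sample$mass_fg[if (exclude_below_lod) !below else TRUE],
       n_below_lod = sum(below))
}

#' Kernel probability density of per-cell masses
#'
#' Gaussian-kernel density estimate of a per-cell mass distribution,
#' evaluated on a regular grid spanning 0 to 1.1 times the largest mass.
#' Cells flagged below the mass limit of detection are excluded (their
#' count is reported, never imputed), as is standard when an element's
#' distribution sits partly under the detection floor. Bandwidth defaults
#' to Silverman's rule on the usable masses.
#'
#' @param sample A `cell_mass_sample` (or any data frame with `mass_fg` and
#'   optionally `below_lod`). At least 5 usable masses.
#' @param bandwidth Kernel bandwidth in fg, or `"auto"` (Silverman).
#' @param normalisation `"area_one"` (trapezoid integral over the grid is
#'   exactly 1; the default and canonical choice) or `"max_one"` (peak
#'   scaled to 1, convenient for overlaying populations).
#' @param n_grid Number of grid points.
#' @return A tibble of class `density_curve` with columns `grid_fg`,
#'   `density`; attributes `bandwidth_fg`, `normalisation`, `n_used`,
#'   `n_below_lod`.
#' @export
probability_density <- function(sample, bandwidth = "auto",
                                normalisation = c("area_one", "max_one"),
                                n_grid = 512) {
  normalisation <- match.arg(normalisation)
  u <- usable_masses(sample)
  m <- u$masses
  if (length(m) < 5) {
    stop("insufficient cells for density (need >= 5 masses above LOD)",
         call. = FALSE)
  }
  bw <- if (identical(bandwidth, "auto")) {
    b <- stats::bw.nrd0(m)
    # Silverman degenerates to 0 on (near-)constant samples; fall back to a
    # small fraction of the location so the curve stays finite.
    if (b <= 0) max(mean(m), 1) * 0.01 else b
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  upper <- max(m) * 1.1
  if (upper <= 0) upper <- 1
  d <- stats::density(m, bw = bw, from = 0, to = upper, n = n_grid)
  dens <- d$y
  if (normalisation == "area_one") {
    area <- trapezoid(d$x, dens)
    dens <- dens / area
  } else {
    dens <- dens / max(dens)
  }
  out <- tibble::tibble(grid_fg = d$x, density = dens)
  structure(out, class = c("density_curve", class(out)),
            bandwidth_fg = bw, normalisation = normalisation,
            n_used = length(m), n_below_lod = u$n_below_lod)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Summary statistics of a per-cell mass distribution
#'
#' The heterogeneity read-out for one population: location (median, mean),
#' spread (SD, CV, IQR, 5th/95th percentiles) and the fraction of detected
#' cells whose mass fell below the detection limit. A tightly regulated
#' element shows a low CV and narrow IQR; heterogeneity shows up as a high
#' CV and wide quantile span. The numbers are reported, not tested — pair
#' with [compare_populations()] for an inferential comparison.
#'
#' @param sample A `cell_mass_sample` (>= 2 usable masses).
#' @return A one-row tibble: `n_cells`, `n_below_lod`, `frac_below_lod`,
#'   `median_fg`, `mean_fg`, `sd_fg`, `cv`, `iqr_fg`, `q05_fg`, `q95_fg`.
#' @examples
#' heterogeneity_summary(tibble::tibble(mass_fg = c(10, 10, 10)))
#' @export
heterogeneity_summary <- function(sample) {
  u <- usable_masses(sample)
  m <- u$masses
  if (length(m) < 2) stop("at least 2 masses required", call. = FALSE)
  q <- stats::quantile(m, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  mu <- mean(m)
  s <- stats::sd(m)
  tibble::tibble(
    n_cells = length(m),
    n_below_lod = u$n_below_lod,
    frac_below_lod = u$n_below_lod / (length(m) + u$n_below_lod),
    median_fg = q[3],
    mean_fg = mu,
    sd_fg = s,
    cv = if (mu > 0) s / mu else NA_real_,
    iqr_fg = q[4] - q[2],
    q05_fg = q[1],
    q95_fg = q[5]
  )
}

#' Compare two per-cell mass populations
#'
#' Nonparametric divergence report for two populations (e.g. infected
#' versus uninfected macrophages): the two-sample Kolmogorov-Smirnov
#' statistic (maximum ECDF difference), plus seeded bootstrap percentile
#' confidence intervals on the median difference (b - a) and the CV ratio
#' (b / a). Deterministic for a fixed seed.
#'
#' @param a,b `cell_mass_sample`s (below-LOD cells excluded).
#' @param n_boot Bootstrap replicates; fewer than 100 is accepted but
#'   flagged in the report.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level for the percentile intervals.
#' @return An object of class `population_comparison`: list with
#'   `ks_statistic`, `median_diff`, `median_diff_ci`, `cv_ratio`,
#'   `cv_ratio_ci`, `n_a`, `n_b`, `n_boot`, `seed`, `warnings`.
#' @export
compare_populations <- function(a, b, n_boot = 1000, seed = 1,
                                conf_level = 0.95) {
  ma <- usable_masses(a)$masses
  mb <- usable_masses(b)$masses
  if (length(ma) == 0 || length(mb) == 0) {
    stop("both samples must contain usable masses", call. = FALSE)
  }
  warnings <- character()
  if (n_boot < 100) {
    warnings <- c(warnings, sprintf("n_boot = %d < 100: intervals unreliable", n_boot))
  }
  ks <- suppressWarnings(stats::ks.test(ma, mb))$statistic

  cv <- function(x) stats::sd(x) / mean(x)
  stat_fun <- function(xa, xb) {
    c(median_diff = stats::median(xb) - stats::median(xa),
      cv_ratio = cv(xb) / cv(xa))
  }
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stat_fun(sample(ma, length(ma), replace = TRUE),
               sample(mb, length(mb), replace = TRUE))
    }, numeric(2))
  })
  alpha <- (1 - conf_level) / 2
  obs <- stat_fun(ma, mb)
  structure(list(
    ks_statistic = unname(ks),
    median_diff = unname(obs["median_diff"]),
    median_diff_ci = unname(stats::quantile(boot["median_diff", ],
                                            c(alpha, 1 - alpha), names = FALSE)),
    cv_ratio = unname(obs["cv_ratio"]),
    cv_ratio_ci = unname(stats::quantile(boot["cv_ratio", ],
                                         c(alpha, 1 - alpha), names = FALSE)),
    n_a = length(ma), n_b = length(mb),
    n_boot = n_boot, seed = seed, conf_level = conf_level,
    warnings = warnings
  ), class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("<population_comparison> n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  KS statistic        %.4f\n", x$ks_statistic))
  cat(sprintf("  median diff (b - a) %.3f fg  [%.3f, %.3f] (%.0f%% bootstrap, %d reps)\n",
              x$median_diff, x$median_diff_ci[1], x$median_diff_ci[2],
              100 * x$conf_level, x$n_boot))
  cat(sprintf("  CV ratio (b / a)    %.3f     [%.3f, %.3f]\n",
              x$cv_ratio, x$cv_ratio_ci[1], x$cv_ratio_ci[2]))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Peak-count reduction relative to a reference condition
#'
#' Quality metric for fixation comparisons: the percentage drop in detected
#' single-cell peaks under a test condition relative to a reference
#' fixation, at constant cell number concentration. A drop signals that
#' fewer cells retained enough analyte to clear the detection threshold,
#' i.e. analyte leaching. Negative values (a gain) are returned as-is.
#'
#' @param n_reference Peak count under the reference condition; > 0.
#' @param n_condition Peak count under the test condition.
#' @return Percent reduction, `100 * (n_reference - n_condition) / n_reference`.
#' @examples
#' peak_reduction_pct(100, 45) # 55
#' @export
peak_reduction_pct <- function(n_reference, n_condition) {
  if (any(n_reference <= 0)) stop("reference peak count must be positive", call. = FALSE)
  100 * (n_reference - n_condition) / n_reference
}

#' Cell recovery after a preparation step
#'
#' Percent of cells surviving fixation/washing, with a pass flag against
#' the working criterion (>= 70% recovery by default).
#'
#' @param count_before,count_after Cell concentrations (cells/mL) before and
#'   after the step; `count_before` > 0.
#' @param threshold_pct Pass threshold in percent.
#' @return A one-row tibble: `recovery_pct`, `pass`.
#' @examples
#' cell_recovery_pct(100, 88)
#' @export
cell_recovery_pct <- function(count_before, count_after, threshold_pct = 70) {
  if (any(count_before <= 0)) stop("count_before must be positive", call. = FALSE)
  pct <- 100 * count_after / count_before
  tibble::tibble(recovery_pct = pct, pass = pct >= threshold_pct)
}

#' Count stability between two time points
#'
#' A suspension counts as stable when the later mean count lies within one
#' baseline standard deviation of the baseline mean — the usual rule for
#' accepting that a fixed suspension has not degraded between counting and
#' analysis.
#'
#' @param baseline Replicate counts at time zero (>= 2, so SD is defined).
#' @param later Replicate counts at the later time point.
#' @return A one-row tibble: `baseline_mean`, `baseline_sd`, `later_mean`,
#'   `abs_shift`, `stable`.
#' @examples
#' count_stability(c(95, 100, 105), c(101, 103, 108))
#' @export
count_stability <- function(baseline, later) {
  if (length(baseline) < 2) {
    stop("baseline needs >= 2 replicates (SD undefined otherwise)", call. = FALSE)
  }
  bm <- mean(baseline)
  bs <- stats::sd(baseline)
  lm_ <- mean(later)
  tibble::tibble(
    baseline_mean = bm, baseline_sd = bs, later_mean = lm_,
    abs_shift = abs(lm_ - bm),
    stable = abs(lm_ - bm) <= bs
  )
}
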