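#' Plot a dwell-resolved trace
#'
#' Time-resolved counts with, optionally, the converged background
#' threshold overlaid — the standard visual check that detected spikes are
#' single-cell events and not background excursions.
#'
#' @param object An [icp_trace()].
#' @param background Optional `background_model` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.icp_trace <- function(object, background = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$counts)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "counts per dwell",
                  title = attr(object, "element") %||% NULL) +
    ggplot2::theme_minimal()
  if (!is.null(background)) {
    p <- p + ggplot2::geom_hline(yintercept = background$threshold_counts,
                                 colour = "firebrick", linetype = "dashed") +
      ggplot2::geom_hline(yintercept = background$mean_counts,
                          colour = "steelblue", linetype = "dotted")
  }
  p
}

#' Plot a per-cell mass density curve
#'
#' @param object A `density_curve` from [probability_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.density_curve <- function(object, ...) {
  ylab <- switch(attr(object, "normalisation"),
                 area_one = "probability density (1/fg)",
                 max_one = "relative probability (arb.)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid_fg, y = .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "mass per cell (fg)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Overlay mass density curves from several populations
#'
#' The population-comparison figure: one normalised density curve per
#' population (e.g. monocytes, uninfected and infected macrophages), on a
#' common mass axis.
#'
#' @param samples Named list of `cell_mass_sample`s.
#' @param normalisation Passed to [probability_density()]; `max_one` is the
#'   usual choice for overlays.
#' @param ... Passed to [probability_density()].
#' @return A ggplot object.
#' @export
plot_population_densities <- function(samples, normalisation = "max_one", ...) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  curves <- purrr::imap_dfr(samples, function(s, nm) {
    d <- probability_density(s, normalisation = normalisation, ...)
    dplyr::mutate(tibble::as_tibble(d), population = nm)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$grid_fg, y = .data$density,
                                       colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mass per cell (fg)",
                  y = if (normalisation == "max_one")
                    "relative probability (arb.)" else "probability density (1/fg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$conc_ng_L, y = .data$corrected_counts)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "concentration (ng/L)",
                  y = if (object$is_corrected) "IS-corrected counts per dwell"
                      else "counts per dwell",
                  subtitle = sprintf("slope %.4g, r² = %.4f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}
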