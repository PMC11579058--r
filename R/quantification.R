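#' Fit a dissolved-standard calibration curve
#'
#' Ordinary least squares of counts per dwell against standard
#' concentration (ng/L). When internal-standard counts are supplied,
#' analyte counts are first divided by the per-standard IS ratio
#' (`is_counts / mean(is_counts)`), which removes multiplicative
#' instrumental drift common to both channels; with constant IS counts the
#' correction is a no-op. The fitted intercept is retained (and subtracted
#' during quantification) rather than forcing the line through the origin,
#' preserving the OLS contract and an honest r-squared.
#'
#' @param standards A data frame with columns `conc_ng_L`, `counts`, and
#'   optionally `is_counts` (internal-standard counts, e.g. 115In at a fixed
#'   added concentration). At least 3 standards including a blank.
#' @return An object of class `calibration_fit`: list with `slope` (counts
#'   per (ng/L) per dwell), `intercept`, `r_squared`, `is_corrected`,
#'   `conc_range`, `standards` (tibble with the corrected response), and the
#'   underlying `lm` fit.
#' @examples
#' std <- tibble::tibble(conc_ng_L = c(0, 100, 200), counts = c(0, 50, 100))
#' fit_calibration(std)$slope # 0.5
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("conc_ng_L", "counts") %in% names(standards)))
  if (nrow(standards) < 3) {
    stop("at least 3 calibration standards (including a blank) are required",
         call. = FALSE)
  }
  standards <- tibble::as_tibble(standards)
  is_corrected <- "is_counts" %in% names(standards) &&
    !all(is.na(standards$is_counts))
  if (is_corrected) {
    if (any(standards$is_counts <= 0)) {
      stop("internal-standard counts must be positive", call. = FALSE)
    }
    ratio <- standards$is_counts / mean(standards$is_counts)
    standards$corrected_counts <- standards$counts / ratio
  } else {
    standards$corrected_counts <- standards$counts
  }
  fit <- stats::lm(corrected_counts ~ conc_ng_L, data = standards)
  structure(list(
    slope = unname(stats::coef(fit)[["conc_ng_L"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    is_corrected = is_corrected,
    conc_range = range(standards$conc_ng_L),
    standards = standards,
    fit = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.4g counts/(ng/L)/dwell, intercept %.4g, r2 %.4f%s\n",
    x$slope, x$intercept, x$r_squared,
    if (x$is_corrected) ", IS-corrected" else ""))
  cat(sprintf("  %d standards spanning %g-%g ng/L\n", nrow(x$standards),
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Convert net event counts to element mass per cell
#'
#' A single-cell event of `net_counts` (background-subtracted) corresponds
#' to the response the dissolved calibration assigns to the analyte mass
#' delivered in one dwell, scaled by the transport efficiency:
#'
#' \deqn{m_{cell} = \frac{N_{net} \; Q_{L/s} \; t_{dwell} \; TE}{S} \times 10^6 \; \mathrm{fg}}
#'
#' with S the calibration slope in counts per (ng/L) per dwell; the factor
#' 1e6 converts ng to fg. All unit handling goes through the package's
#' central converters.
#'
#' @param net_counts Net (background-subtracted) event counts; vectorised.
#' @param cal A [fit_calibration()] result, or a bare slope in counts per
#'   (ng/L) per dwell.
#' @param te A `transport_efficiency` or a bare fraction in (0, 1].
#' @param flow_mL_min Sample flow, mL/min.
#' @param dwell_time_s Dwell time, s.
#' @return Mass per event in femtograms (numeric, same length as
#'   `net_counts`).
#' @examples
#' mass_per_event(1000, cal = 0.5, te = 0.001,
#'                flow_mL_min = 0.3, dwell_time_s = 0.003) # 0.03 fg
#' @export
mass_per_event <- function(net_counts, cal, te, flow_mL_min, dwell_time_s) {
  slope <- if (inherits(cal, "calibration_fit")) cal$slope else cal
  te_v <- te_value(te)
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  if (!is.finite(te_v) || te_v <= 0) {
    stop("cannot quantify without transport efficiency (TE must be > 0)",
         call. = FALSE)
  }
  if (flow_mL_min <= 0 || dwell_time_s <= 0) {
    stop("flow_mL_min and dwell_time_s must be positive", call. = FALSE)
  }
  mass_ng <- net_counts * flow_L_per_s(flow_mL_min) * dwell_time_s * te_v / slope
  ng_to_fg(mass_ng)
}

#' Quantify an event table into a per-cell mass sample
#'
#' Applies [mass_per_event()] to every detected event and marks events whose
#' mass falls below the per-event mass limit of detection
#' ([event_mass_lod()]). Below-LOD events are kept in the table (flagged,
#' never imputed) so that downstream population analysis can report the
#' excluded fraction.
#'
#' @inheritParams mass_per_event
#' @param events An `event_table` from [extract_events()].
#' @param flow_mL_min,dwell_time_s Acquisition settings; default to the
#'   values carried on the event table.
#' @return A tibble of class `cell_mass_sample` with columns `event_id`,
#'   `net_counts`, `mass_fg`, `below_lod`; attributes carry the mass LOD
#'   (fg), TE, slope and acquisition settings used.
#' @export
quantify_events <- function(events, cal, te, flow_mL_min = NULL,
                            dwell_time_s = NULL) {
  stopifnot(inherits(events, "event_table"))
  flow_mL_min <- flow_mL_min %||% attr(events, "flow_mL_min")
  dwell_time_s <- dwell_time_s %||% attr(events, "dwell_time_s")
  bg <- attr(events, "background")
  mass <- mass_per_event(events$net_counts, cal, te, flow_mL_min, dwell_time_s)
  lod_fg <- event_mass_lod(bg, cal, te, flow_mL_min, dwell_time_s)
  out <- tibble::tibble(
    event_id = events$event_id,
    net_counts = events$net_counts,
    mass_fg = mass,
    below_lod = mass < lod_fg
  )
  structure(out, class = c("cell_mass_sample", class(out)),
            mass_lod_fg = lod_fg,
            te = te_value(te),
            slope = if (inherits(cal, "calibration_fit")) cal$slope else cal,
            flow_mL_min = flow_mL_min,
            dwell_time_s = dwell_time_s,
            element = attr(events, "element"))
}

#' Dissolved limit of detection
#'
#' The smallest dissolved concentration distinguishable from the blank,
#' using the 3-sigma convention: `LOD = 3 * SD(blank) / slope`. The k
#' multiplier is exposed for labs using 3.29 (IUPAC) or 10 (LOQ).
#'
#' @param blank_counts Replicate blank readings (counts per dwell), >= 3.
#' @param cal A [fit_calibration()] or a bare slope.
#' @param k LOD multiplier, default 3.
#' @return LOD in ng/L.
#' @examples
#' dissolved_lod(c(7, 10, 13), cal = 10) # 0.9 ng/L
#' @export
dissolved_lod <- function(blank_counts, cal, k = 3) {
  slope <- if (inherits(cal, "calibration_fit")) cal$slope else cal
  if (length(blank_counts) < 3) stop("at least 3 blank replicates required", call. = FALSE)
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  k * stats::sd(blank_counts) / slope
}

#' Per-event mass limit of detection
#'
#' The mass corresponding to the smallest net signal the detector threshold
#' can separate from background, i.e. `net_counts = k_sigma * SD(background)`
#' fed through [mass_per_event()]. Events quantified below this mass are
#' flagged (and typically excluded from density curves, with their fraction
#' reported).
#'
#' @param background A `background_model` from [iterative_threshold()].
#' @inheritParams mass_per_event
#' @return Mass LOD in fg.
#' @export
event_mass_lod <- function(background, cal, te, flow_mL_min, dwell_time_s) {
  stopifnot(inherits(background, "background_model"))
  mass_per_event(background$k_sigma * background$sd_counts, cal, te,
                 flow_mL_min, dwell_time_s)
}

#' Mass per cell from a bulk digest
#'
#' The bulk comparator: total analyte in a digested cell pellet divided by
#' the number of cells digested.
#'
#' @param measured_conc_ng_L Concentration measured in the (diluted) digest,
#'   ng/L.
#' @param digest_volume_L Digest volume, L.
#' @param dilution_factor Dilution applied before measurement.
#' @param n_cells Number of cells digested.
#' @return Mass per cell in fg.
#' @examples
#' bulk_mass_per_cell(100, 0.01, 10, 1e7) # 1 fg/cell
#' @export
bulk_mass_per_cell <- function(measured_conc_ng_L, digest_volume_L,
                               dilution_factor = 1, n_cells) {
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (digest_volume_L < 0 || dilution_factor <= 0) {
    stop("digest_volume_L must be >= 0 and dilution_factor > 0", call. = FALSE)
  }
  ng_to_fg(measured_conc_ng_L * digest_volume_L * dilution_factor / n_cells)
}

#' Relative error of bulk versus single-cell mass per cell
#'
#' Bulk digests include cellular debris and leached analyte as well as
#' intact cells, so bulk mass-per-cell systematically exceeds the
#' single-cell mean; the relative error `100 * (bulk - sc) / bulk` is
#' positive in that regime.
#'
#' @param bulk_fg Bulk-derived mass per cell, fg; must be > 0.
#' @param sc_mean_fg Mean single-cell mass, fg.
#' @return Percent relative error (positive when bulk is higher).
#' @examples
#' bulk_vs_sc_relative_error(10, 1) # 90
#' @export
bulk_vs_sc_relative_error <- function(bulk_fg, sc_mean_fg) {
  if (any(bulk_fg <= 0)) stop("bulk mass must be positive", call. = FALSE)
  100 * (bulk_fg - sc_mean_fg) / bulk_fg
}

#' Calibration slope matched to a detector sensitivity
#'
#' Inverts the mass equation: a detector responding with `sens` counts per
#' fg of cell mass corresponds, under transport efficiency `te`, flow `Q`
#' and dwell `t`, to a dissolved calibration slope
#' `S = sens * Q_L/s * t * te * 1e6` counts per (ng/L) per dwell. Used to
#' close the loop between the synthetic-trace generator (which is
#' parameterised by counts/fg) and quantification (parameterised by the
#' dissolved slope).
#'
#' @param sensitivity_counts_per_fg Detector response, counts per fg.
#' @param te Transport efficiency fraction (or `transport_efficiency`).
#' @param flow_mL_min Sample flow, mL/min.
#' @param dwell_time_s Dwell time, s.
#' @return Slope in counts per (ng/L) per dwell.
#' @export
matched_calibration_slope <- function(sensitivity_counts_per_fg, te,
                                      flow_mL_min, dwell_time_s) {
  te_v <- te_value(te)
  stopifnot(sensitivity_counts_per_fg > 0, te_v > 0,
            flow_mL_min > 0, dwell_time_s > 0)
  sensitivity_counts_per_fg * flow_L_per_s(flow_mL_min) * dwell_time_s *
    te_v * 1e6
}
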