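# Unit conversions are centralised here: the dominant failure mode of
# SP/SC-ICP-MS implementations is unit drift between mL/min flows, second
# dwells and ng/L calibrations. Everything downstream calls these.

#' Unit conversion helpers
#'
#' Canonical internal units are litres, seconds and femtograms. Sample flow
#' rates are quoted in mL/min on instruments, calibration slopes in counts
#' per (ng/L) per dwell, and per-cell masses in fg; these helpers perform
#' the conversions in one audited place.
#'
#' @param flow_mL_min Sample uptake rate in mL/min.
#' @param ng Mass in nanograms.
#' @param fg Mass in femtograms.
#' @param seconds Duration in seconds.
#' @return A numeric vector in the target unit.
#' @examples
#' flow_L_per_s(0.3) # 5e-06 L/s
#' ng_to_fg(1)       # 1e6 fg
#' @name units
NULL

#' @rdname units
#' @export
flow_L_per_s <- function(flow_mL_min) {
  stopifnot(is.numeric(flow_mL_min))
  flow_mL_min / 1000 / 60
}

#' @rdname units
#' @export
flow_mL_per_min_to_mL_per_s <- function(flow_mL_min) {
  flow_mL_min / 60
}

#' @rdname units
#' @export
seconds_to_minutes <- function(seconds) seconds / 60

#' @rdname units
#' @export
ng_to_fg <- function(ng) ng * 1e6

#' @rdname units
#' @export
fg_to_ng <- function(fg) fg / 1e6

# Deterministic per-stage seed fan-out: one top-level seed yields a
# reproducible stream of child seeds, kept below 2^31 - 1.
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.numeric(seed) * 48271 + index * 2654435) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
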