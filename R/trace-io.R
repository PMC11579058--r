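#' Construct a dwell-resolved intensity trace
#'
#' An `icp_trace` is a tibble with one row per dwell window, columns
#' `time_s` (window start) and `counts` (integer detector counts), and
#' acquisition metadata carried as attributes. It is the raw observable of
#' time-resolved single-cell ICP-MS: each transient spike above background
#' corresponds to one cell (or a coincidence of cells) ionising in the
#' plasma.
#'
#' @param counts Integer vector of non-negative detector counts, one per
#'   dwell window.
#' @param dwell_time_s Dwell (integration) time in seconds; must be > 0.
#'   Typical values run from 0.003 s (the usual optimum for single-cell
#'   work) up to 0.1 s, where cell transients are no longer resolved.
#' @param element Isotope label, e.g. `"24Mg"`.
#' @param flow_mL_min Sample uptake rate in mL/min (metadata; used by
#'   transport-efficiency and mass calculations downstream).
#' @param nebuliser_gas_L_min Nebuliser gas flow in L/min. Carried as
#'   metadata only; never used in computation.
#' @return A tibble of class `icp_trace` with columns `time_s`, `counts`.
#' @examples
#' tr <- icp_trace(c(10, 12, 11), dwell_time_s = 0.003, element = "24Mg")
#' dwell_time(tr)
#' @export
icp_trace <- function(counts, dwell_time_s, element = NA_character_,
                      flow_mL_min = NA_real_, nebuliser_gas_L_min = NA_real_) {
  if (length(counts) == 0) stop("trace must contain at least one dwell", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be integer-valued: detector counts are integral; ",
         "fractional values indicate a pre-processed file", call. = FALSE)
  }
  if (!is.numeric(dwell_time_s) || length(dwell_time_s) != 1 || dwell_time_s <= 0) {
    stop("dwell_time_s must be a single positive number", call. = FALSE)
  }
  n <- length(counts)
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1) * dwell_time_s,
    counts = as.integer(round(counts))
  )
  structure(out,
            class = c("icp_trace", class(out)),
            dwell_time_s = dwell_time_s,
            element = element,
            flow_mL_min = flow_mL_min,
            nebuliser_gas_L_min = nebuliser_gas_L_min)
}

#' @rdname icp_trace
#' @param trace An `icp_trace`.
#' @export
dwell_time <- function(trace) attr(trace, "dwell_time_s")

#' @rdname icp_trace
#' @export
n_dwells <- function(trace) nrow(trace)

#' @rdname icp_trace
#' @export
acquisition_duration <- function(trace) nrow(trace) * attr(trace, "dwell_time_s")

#' @export
print.icp_trace <- function(x, ...) {
  cat(sprintf("<icp_trace> %s dwells x %.4g s (%.4g s total), element %s\n",
              format(nrow(x), big.mark = ","), dwell_time(x),
              acquisition_duration(x),
              attr(x, "element") %||% NA))
  NextMethod()
}

#' Read a dwell-resolved trace from a text file
#'
#' The canonical on-disk dialect is CSV with a comment header declaring the
#' acquisition metadata, e.g.
#' `# element=24Mg dwell_time_s=0.003 flow_mL_min=0.3`, followed by
#' `time_s,counts` rows. A headerless two-column `time_s,counts` file is
#' also accepted; the dwell time is then inferred from the time spacing,
#' which must be uniform to within 1%.
#'
#' @param path Path to a trace CSV.
#' @return An [icp_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("no data rows in ", path, call. = FALSE)

  meta <- parse_header_meta(header)
  has_col_names <- grepl("^\\s*time_s\\s*,", body[1]) ||
    grepl("^\\s*counts\\s*$", body[1])
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = has_col_names,
                        colClasses = "character")
  if (!has_col_names) {
    names(df) <- if (ncol(df) >= 2) c("time_s", "counts")[seq_len(ncol(df))] else "counts"
  }
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0) {
    stop("malformed row in ", path, " at data line ",
         bad[1] + has_col_names, call. = FALSE)
  }

  if ("time_s" %in% names(df) && nrow(df) >= 2) {
    spacing <- diff(df$time_s)
    dt_inferred <- stats::median(spacing)
    if (any(abs(spacing - dt_inferred) > 0.01 * dt_inferred)) {
      stop("non-uniform time spacing (> 1% deviation); not a fixed-dwell trace",
           call. = FALSE)
    }
  } else {
    dt_inferred <- NA_real_
  }
  dt <- meta$dwell_time_s %||% dt_inferred
  if (is.null(dt) || !is.finite(dt)) {
    stop("dwell time neither declared in header nor inferable from a time column",
         call. = FALSE)
  }
  counts <- df[[if ("counts" %in% names(df)) "counts" else names(df)[ncol(df)]]]
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("fractional counts in ", path,
         ": detector counts are integral; refusing to round", call. = FALSE)
  }
  icp_trace(counts, dwell_time_s = dt,
            element = meta$element %||% NA_character_,
            flow_mL_min = meta$flow_mL_min %||% NA_real_,
            nebuliser_gas_L_min = meta$nebuliser_gas_L_min %||% NA_real_)
}

#' Write a trace to the canonical CSV dialect
#'
#' Lossless for counts (written as integers) and dwell time (written to full
#' double precision in the header), so `read_trace(write_trace(x))`
#' round-trips exactly.
#'
#' @param trace An [icp_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "icp_trace"))
  meta <- sprintf("# element=%s dwell_time_s=%s flow_mL_min=%s",
                  attr(trace, "element") %||% NA,
                  format(dwell_time(trace), digits = 17),
                  format(attr(trace, "flow_mL_min") %||% NA, digits = 17))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,counts", con)
  writeLines(sprintf("%s,%d", format(trace$time_s, digits = 17, trim = TRUE,
                                     scientific = FALSE),
                     trace$counts), con)
  invisible(path)
}

parse_header_meta <- function(header_lines) {
  meta <- list()
  for (ln in header_lines) {
    kv <- regmatches(ln, gregexpr("[A-Za-z_][A-Za-z0-9_]*=[^ ]+", ln))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      key <- parts[1]
      val <- parts[2]
      if (key == "element") {
        meta[[key]] <- val
      } else if (val == "NA") {
        meta[[key]] <- NA_real_
      } else {
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      }
    }
  }
  if (!is.null(meta$element) && meta$element %in% c("NA", "")) meta$element <- NA_character_
  meta
}

#' Summarise hemocytometer replicate counts into a cell suspension record
#'
#' Triplicate hemocytometer counts are the standard way to establish the
#' cell number concentration that the pulse-frequency transport-efficiency
#' method requires. The suspension concentration is the replicate mean;
#' a Trypan-blue viability fraction can be carried to weight the count of
#' intact (analysable) cells.
#'
#' @param replicate_counts Numeric vector of replicate concentrations
#'   (cells/mL); at least one value.
#' @param viability_fraction Optional fraction of viable cells in 0..1.
#' @return A one-row tibble of class `cell_suspension` with columns
#'   `cells_per_mL`, `sd_cells_per_mL`, `n_replicates`, `viability_fraction`.
#' @examples
#' cell_suspension(c(4.8e5, 5.1e5, 5.0e5))
#' @export
cell_suspension <- function(replicate_counts, viability_fraction = NA_real_) {
  if (length(replicate_counts) < 1 || any(replicate_counts <= 0)) {
    stop("replicate_counts must contain at least one positive count", call. = FALSE)
  }
  if (!is.na(viability_fraction) &&
      (viability_fraction < 0 || viability_fraction > 1)) {
    stop("viability_fraction must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(
    cells_per_mL = mean(replicate_counts),
    sd_cells_per_mL = if (length(replicate_counts) >= 2) stats::sd(replicate_counts) else NA_real_,
    n_replicates = length(replicate_counts),
    viability_fraction = viability_fraction
  )
  structure(out, class = c("cell_suspension", class(out)),
            replicate_counts = replicate_counts)
}
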