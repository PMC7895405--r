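# Lymphocyte gating and B-cell selection.

#' Gate lymphocytes on CD45-high / SSC-low
#'
#' Rectangular gate retaining events with CD45 at or above `cd45_min` and SSC
#' at or below `ssc_max`. The input is never mutated; applying the gate twice
#' is idempotent. An empty gate yields an empty table with a warning, not an
#' error.
#'
#' @param events Event tibble with at least `CD45` and `SSC` columns.
#' @param cd45_min,ssc_max Gate thresholds (linear scale); defaults from
#'   [gate_defaults()].
#' @return The gated subset of `events`.
#' @export
#' @examples
#' ev <- tibble::tibble(CD45 = c(600, 20), SSC = c(120, 900), CD19 = c(5, 5))
#' gate_lymphocytes(ev)
gate_lymphocytes <- function(events, cd45_min = gate_defaults()$cd45_min,
                             ssc_max = gate_defaults()$ssc_max) {
  stopifnot(all(c("CD45", "SSC") %in% names(events)))
  out <- events[events$CD45 >= cd45_min & events$SSC <= ssc_max, , drop = FALSE]
  if (nrow(out) == 0) warn("lymphocyte gate is empty")
  out
}

#' Isotype-derived positivity threshold
#'
#' The fluorescence level above which an event is called positive: the 99.5th
#' percentile of the isotype-control distribution, by midpoint interpolation
#' between order statistics (for values `1..1000` the threshold is 995.5).
#' This bounds the false-positive event rate at 0.5%.
#'
#' @param isotype_values Numeric vector of control fluorescence values
#'   (at least 100, otherwise the tail percentile is unreliable and an error
#'   is raised).
#' @param percentile Percentile to use, in (0, 100); default 99.5.
#' @return The threshold value.
#' @export
#' @examples
#' positivity_threshold(1:1000)
positivity_threshold <- function(isotype_values, percentile = 99.5) {
  isotype_values <- isotype_values[!is.na(isotype_values)]
  if (length(isotype_values) < 100) {
    abort("positivity threshold needs at least 100 isotype-control values")
  }
  stopifnot(percentile > 0, percentile < 100)
  unname(quantile(isotype_values, probs = percentile / 100, type = 5))
}

#' Select CD19+ B cells from gated lymphocytes
#'
#' Retains lymphocyte events whose CD19 exceeds the positivity threshold
#' derived from the isotype control's CD19 distribution. Fewer than 100
#' retained B cells flags the sample low-yield (attribute `low_yield`, plus a
#' warning); quantification may still proceed.
#'
#' @param lymphocytes Gated stained-tube events (must contain `CD19`).
#' @param isotype Gated isotype-control events (must contain `CD19`).
#' @param percentile Threshold percentile, see [positivity_threshold()].
#' @return The CD19+ subset of `lymphocytes`.
#' @export
select_b_cells <- function(lymphocytes, isotype, percentile = 99.5) {
  stopifnot("CD19" %in% names(lymphocytes), "CD19" %in% names(isotype))
  thr <- positivity_threshold(isotype$CD19, percentile)
  out <- lymphocytes[lymphocytes$CD19 > thr, , drop = FALSE]
  if (nrow(out) < 100) {
    warn(sprintf("low B-cell yield: %d CD19+ events", nrow(out)))
    attr(out, "low_yield") <- TRUE
  }
  out
}
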