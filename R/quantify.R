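# Per-marker quantification: percent-positive, MFIR, intensity pattern.

#' Percent of B cells positive for a marker
#'
#' 100 times the fraction of gated B-cell events whose fluorescence exceeds
#' the isotype-derived positivity threshold. Invariant under any strictly
#' monotone rescaling applied jointly to marker and isotype values.
#'
#' @param marker_values Marker fluorescence of the gated B cells (non-empty).
#' @param isotype_values Isotype-control values for the same marker.
#' @param percentile Threshold percentile, see [positivity_threshold()].
#' @return Percent positive in \[0, 100\].
#' @export
#' @examples
#' percent_positive(c(rep(1, 140), rep(100, 60)), runif(200, 0, 10))
percent_positive <- function(marker_values, isotype_values, percentile = 99.5) {
  if (length(marker_values) == 0) abort("no B-cell events to quantify")
  thr <- positivity_threshold(isotype_values, percentile)
  100 * sum(marker_values > thr) / length(marker_values)
}

#' Mean fluorescence intensity ratio (MFIR)
#'
#' MFI of the stained B cells divided by the MFI of the isotype control, with
#' "mean fluorescence intensity" taken literally as the arithmetic mean on
#' the linear scale (the median is available as an option). Scale-invariant:
#' `mfir(a*x, a*y) == mfir(x, y)` for any positive `a`. A positivity cutoff
#' of 18 on this ratio is the conventional CD200 criterion.
#'
#' @param marker_values Marker fluorescence of the gated B cells.
#' @param isotype_values Isotype-control values (mean must be positive).
#' @param stat `"mean"` (default) or `"median"`.
#' @return The ratio (finite, >= 0).
#' @export
#' @examples
#' mfir(rep(50, 10), rep(2, 10))
mfir <- function(marker_values, isotype_values, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(marker_values) == 0 || length(isotype_values) == 0) {
    abort("mfir needs non-empty marker and isotype values")
  }
  f <- if (stat == "mean") mean else median
  denom <- f(isotype_values)
  if (!is.finite(denom) || denom <= 0) abort("isotype MFI must be positive")
  f(marker_values) / denom
}

#' Log-decade expression pattern
#'
#' Classifies the positive population's intensity by the log decade of its
#' median on the four-decade scale: weak in \[1, 10), moderate in \[10, 100),
#' strong at or above 100. With no positive events the pattern is "weak" by
#' convention and the value is flagged (attribute `flagged`).
#'
#' @param positive_values Fluorescence of the positive events (those above
#'   the positivity threshold).
#' @return One of `"weak"`, `"moderate"`, `"strong"`.
#' @export
#' @examples
#' expression_pattern(rep(50, 5))
expression_pattern <- function(positive_values) {
  positive_values <- positive_values[!is.na(positive_values)]
  if (length(positive_values) == 0) {
    out <- "weak"
    attr(out, "flagged") <- TRUE
    return(out)
  }
  m <- median(positive_values)
  if (m >= 100) "strong" else if (m >= 10) "moderate" else "weak"
}

#' Quantify every panel marker for one sample
#'
#' Full single-sample analysis: gate lymphocytes in the stained and isotype
#' tubes, select CD19+ B cells against the isotype threshold, then compute
#' percent-positive, MFIR and expression pattern for each panel marker.
#' Deterministic given its inputs.
#'
#' @param events Stained-tube event tibble.
#' @param isotype Matched isotype-control tibble.
#' @param sample_id Identifier used in messages and the output.
#' @param gate Gate thresholds, a list as [gate_defaults()].
#' @param percentile Positivity percentile, see [positivity_threshold()].
#' @param mfir_stat Statistic for [mfir()], `"mean"` or `"median"`.
#' @param markers Markers to quantify (default the full panel).
#' @return A tibble with one row per marker: `sample_id`, `marker`,
#'   `percent_positive`, `mfir`, `pattern`, `n_lymphocytes`, `n_b_cells`.
#' @export
#' @examples
#' d <- cohort_design(c("CLL-typical" = 1))
#' sim <- simulate_sample(d[1, ], master_seed = 5, n_events = 4000, n_isotype = 2000)
#' analyze_sample(sim$events, sim$isotype, sample_id = "S001")
analyze_sample <- function(events, isotype, sample_id = "sample",
                           gate = gate_defaults(), percentile = 99.5,
                           mfir_stat = "mean", markers = panel_markers()) {
  missing_cols <- setdiff(c("CD19", markers), names(events))
  if (length(missing_cols) > 0) {
    abort(paste0(sample_id, ": event table lacks column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  lym <- gate_lymphocytes(events, gate$cd45_min, gate$ssc_max)
  lym_iso <- gate_lymphocytes(isotype, gate$cd45_min, gate$ssc_max)
  if (nrow(lym) == 0 || nrow(lym_iso) == 0) {
    abort(paste0(sample_id, ": empty lymphocyte gate"))
  }
  b <- suppressWarnings(select_b_cells(lym, lym_iso, percentile))
  if (nrow(b) == 0) abort(paste0(sample_id, ": no CD19+ B cells in gate"))
  if (nrow(b) < 100) {
    warn(sprintf("%s: low B-cell yield (%d events)", sample_id, nrow(b)))
  }
  purrr::map_dfr(markers, function(m) {
    thr <- positivity_threshold(lym_iso[[m]], percentile)
    pos <- b[[m]][b[[m]] > thr]
    tibble(
      sample_id = sample_id, marker = m,
      percent_positive = percent_positive(b[[m]], lym_iso[[m]], percentile),
      mfir = mfir(b[[m]], lym_iso[[m]], mfir_stat),
      pattern = as.character(expression_pattern(pos)),
      n_lymphocytes = nrow(lym), n_b_cells = nrow(b)
    )
  })
}

#' Analyze every sample of a generated cohort
#'
#' Reads the per-sample event and isotype CSVs referenced by a manifest and
#' runs [analyze_sample()] on each.
#'
#' @param manifest Manifest tibble from [generate_cohort()] (or the same CSV
#'   contract for real listmode exports).
#' @inheritParams analyze_sample
#' @return Stacked per-marker results, one row per sample and marker.
#' @export
analyze_cohort <- function(manifest, gate = gate_defaults(), percentile = 99.5,
                           mfir_stat = "mean") {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    ev <- readr::read_csv(manifest$events_path[i], show_col_types = FALSE,
                          progress = FALSE)
    iso <- readr::read_csv(manifest$isotype_path[i], show_col_types = FALSE,
                           progress = FALSE)
    analyze_sample(ev, iso, sample_id = manifest$sample_id[i], gate = gate,
                   percentile = percentile, mfir_stat = mfir_stat)
  })
}
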