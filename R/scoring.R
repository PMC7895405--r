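# The three immunophenotypic scoring systems.
#
# Point rules (per marker, applied to one sample's quantification):
#   CD5, CD23, CD200: 1 point iff percent-positive >= 30 (boundary inclusive)
#   FMC7, CD79b:      1 point iff percent-positive < 30 (strict)
#   sIgM:             1 point iff the expression pattern is weak
# Classical Matutes score = CD5 + CD23 + FMC7 + CD79b + sIgM   (0-5)
# CD200-augmented score  = classical + CD200                   (0-6)
# Four-marker score      = CD5 + CD23 + sIgM + CD200           (0-4)

#' Marker points for one sample
#'
#' Applies the point rules to a one-sample quantification table. In
#' `cd200_mode = "mfir"` the CD200 point is scored by MFIR >= 18 instead of
#' percent-positive >= 30 (the default, used by all three score systems).
#'
#' @param results One sample's rows from [analyze_sample()] (columns
#'   `marker`, `percent_positive`, `mfir`, `pattern`).
#' @param cd200_mode `"percent"` (default) or `"mfir"`.
#' @return Named integer vector of 0/1 points for CD5, CD23, FMC7, CD79b,
#'   sIgM and CD200.
#' @export
#' @examples
#' res <- tibble::tibble(
#'   marker = c("CD5", "CD23", "FMC7", "CD79b", "sIgM", "CD200"),
#'   percent_positive = c(95, 80, 10, 20, 90, 98),
#'   mfir = c(40, 30, 2, 3, 5, 59), pattern = c(rep("strong", 4), "weak", "strong"))
#' marker_points(res)
marker_points <- function(results, cd200_mode = c("percent", "mfir")) {
  cd200_mode <- match.arg(cd200_mode)
  needed <- c(score_markers_classical(), "CD200")
  missing_m <- setdiff(needed, results$marker)
  if (length(missing_m) > 0) {
    abort(paste("marker(s) missing from results:", paste(missing_m, collapse = ", ")))
  }
  g <- function(m, col) results[[col]][match(m, results$marker)]
  pts <- c(
    CD5   = g("CD5", "percent_positive") >= 30,
    CD23  = g("CD23", "percent_positive") >= 30,
    FMC7  = g("FMC7", "percent_positive") < 30,
    CD79b = g("CD79b", "percent_positive") < 30,
    sIgM  = g("sIgM", "pattern") == "weak",
    CD200 = if (cd200_mode == "percent") g("CD200", "percent_positive") >= 30
            else g("CD200", "mfir") >= 18
  )
  vapply(pts, as.integer, integer(1))
}

check_points <- function(points, needed) {
  missing_m <- setdiff(needed, names(points))
  if (length(missing_m) > 0) {
    abort(paste("point(s) missing:", paste(missing_m, collapse = ", ")))
  }
  if (!all(points[needed] %in% c(0L, 1L))) abort("points must be 0 or 1")
}

#' Classical five-marker Matutes score
#' @param points Named 0/1 vector from [marker_points()].
#' @return Integer score 0-5.
#' @export
classical_score <- function(points) {
  check_points(points, score_markers_classical())
  as.integer(sum(points[score_markers_classical()]))
}

#' CD200-augmented Matutes score
#' @inheritParams classical_score
#' @return Integer score 0-6 (classical score plus the CD200 point).
#' @export
cd200_augmented_score <- function(points) {
  check_points(points, c(score_markers_classical(), "CD200"))
  classical_score(points) + as.integer(points[["CD200"]])
}

#' Simplified four-marker score (CD5, CD23, sIgM, CD200)
#' @inheritParams classical_score
#' @return Integer score 0-4.
#' @export
four_marker_score <- function(points) {
  check_points(points, score_markers_four())
  as.integer(sum(points[score_markers_four()]))
}

#' Classify a score into typical CLL / atypical CLL / non-CLL
#'
#' A score of 4 or more is typical CLL, exactly 3 is atypical CLL, 2 or less
#' is non-CLL. The binary diagnostic screen used for sensitivity and
#' specificity is score >= 4 for every system; atypical CLL is a reporting
#' category, not a third class in accuracy computations.
#'
#' @param score Integer score(s).
#' @param system `"classical"` (0-5), `"augmented"` (0-6) or
#'   `"four_marker"` (0-4); out-of-range scores raise an error.
#' @return Character vector in `{"typical-CLL", "atypical-CLL", "non-CLL"}`.
#' @export
#' @examples
#' classify_sample(c(5, 3, 0), "classical")
classify_sample <- function(score, system = c("classical", "augmented", "four_marker")) {
  system <- match.arg(system)
  top <- c(classical = 5L, augmented = 6L, four_marker = 4L)[[system]]
  if (any(score < 0 | score > top | score != floor(score))) {
    abort(sprintf("score out of range 0-%d for the %s system", top, system))
  }
  ifelse(score >= 4, "typical-CLL", ifelse(score == 3, "atypical-CLL", "non-CLL"))
}

#' Score every sample of a cohort
#'
#' Applies the three scoring systems to a stacked quantification table.
#'
#' @param results Output of [analyze_cohort()] (or stacked
#'   [analyze_sample()] rows for several samples).
#' @inheritParams marker_points
#' @return A tibble with one row per sample: the six marker points, the
#'   three scores and the three classifications (`class_*` columns).
#' @export
score_cohort <- function(results, cd200_mode = c("percent", "mfir")) {
  cd200_mode <- match.arg(cd200_mode)
  results %>%
    group_by(.data$sample_id) %>%
    dplyr::group_modify(function(df, key) {
      pts <- marker_points(df, cd200_mode)
      tibble(
        !!!as.list(setNames(as.integer(pts), paste0("pt_", names(pts)))),
        classical_score = classical_score(pts),
        augmented_score = cd200_augmented_score(pts),
        four_marker_score = four_marker_score(pts)
      )
    }) %>%
    ungroup() %>%
    mutate(
      class_classical = classify_sample(.data$classical_score, "classical"),
      class_augmented = classify_sample(.data$augmented_score, "augmented"),
      class_four_marker = classify_sample(.data$four_marker_score, "four_marker")
    )
}
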