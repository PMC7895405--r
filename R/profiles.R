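# Per-patient marker profiles: numeric generation targets drawn inside the
# supports a case card fixes.

# Fluorescence model constants: four-decade linear scale [1, 1e4], isotype /
# negative component a log-normal centred in the first decade. The 99.5th
# percentile of this component (~4.9) sits well below the weak-positive
# median of 8, so even "weak" populations clear the positivity threshold.
iso_params <- function() {
  sdlog <- 0.35
  list(meanlog = log(2), sdlog = sdlog, mean = 2 * exp(sdlog^2 / 2))
}

# Positive-population intensity targets by pattern class: the generated
# median falls in the decade the pattern rule assigns (weak [1,10),
# moderate [10,100), strong >= 100).
pattern_intensity <- function(pattern) {
  p <- c(weak = 8, moderate = 40, strong = 300)[pattern]
  sd <- c(weak = 0.15, moderate = 0.25, strong = 0.25)[pattern]
  list(mean = unname(p * exp(sd^2 / 2)), sdlog = unname(sd))
}

# Draw from a bounded unimodal distribution with an exact median: a Beta(2,2)
# deviate mapped piecewise-linearly through (lo, med, hi). Degenerate
# lo = med = hi gives a point mass.
rbounded <- function(n, lo, med, hi) {
  if (any(lo > med | med > hi)) {
    abort("empty or inverted support: need lo <= med <= hi")
  }
  u <- rbeta(n, 2, 2)
  ifelse(u <= 0.5, lo + (med - lo) * 2 * u, med + (hi - med) * (2 * u - 1))
}

pct_high <- c(40, 85, 98)   # targets for markers designed >= 30% positive
pct_low  <- c(2, 8, 20)     # targets for markers designed < 30% positive

#' Draw one patient's marker profile from a design card
#'
#' Samples numeric generation targets (per-marker percent-positive, positive
#' population intensity, and the CD200 MFIR) inside the supports of one
#' cohort-design row. Values respect the card supports by construction, and
#' repeated calls with the same seed are identical.
#'
#' The CD200 positive-population mean is solved from the MFIR target: with
#' positive fraction `p`, isotype mean `i` and target ratio `r`, the B-cell
#' mixture mean is `(1-p)*i + p*m`, so `m = i*(r - (1-p))/p`, floored at 20
#' linear units. For CD200-negative cards the ratio target is first clamped
#' to the range that floor allows.
#'
#' @param design_row One row of [cohort_design()].
#' @param seed Integer seed for the draw (derive it from a master seed with
#'   one stream per sample for reproducible cohorts).
#' @return A tibble with one row per panel marker: `sample_id`, `diagnosis`,
#'   `subtype`, `marker`, `pct_target`, `pos_mean`, `pos_sdlog`, `iso_mean`,
#'   `sigm_pattern`, `cd200_mfir_target`, `b_frac`.
#' @export
#' @examples
#' d <- cohort_design(c("CLL-typical" = 1))
#' sample_patient_profile(d[1, ], seed = 7)
sample_patient_profile <- function(design_row, seed = 1L) {
  stopifnot(nrow(design_row) == 1)
  iso <- iso_params()
  with_local_seed(seed, {
    pick <- function(pt) if (pt == 1L) pct_high else pct_low
    pct <- c(
      CD20  = rbounded(1, 85, 93, 99),
      CD5   = rbounded1(pick(design_row$pt_CD5)),
      CD23  = rbounded1(pick(design_row$pt_CD23)),
      # FMC7/CD79b score a point when *below* 30%: point 1 means a low target
      FMC7  = rbounded1(if (design_row$pt_FMC7 == 1L) pct_low else pct_high),
      CD79b = rbounded1(if (design_row$pt_CD79b == 1L) pct_low else pct_high),
      CD200 = rbounded(1, design_row$cd200_lo, design_row$cd200_med, design_row$cd200_hi),
      sIgM  = rbounded(1, 85, 93, 99),
      CD10  = if (design_row$subtype == "FL") rbounded(1, 60, 80, 95) else rbounded(1, 1, 3, 10)
    )
    pos_mean <- c(
      CD20 = rbounded(1, 100, 180, 300), CD5 = rbounded(1, 100, 180, 300),
      CD23 = rbounded(1, 100, 180, 300), FMC7 = rbounded(1, 100, 180, 300),
      CD79b = rbounded(1, 100, 180, 300), CD200 = NA_real_,
      sIgM = NA_real_, CD10 = rbounded(1, 100, 180, 300)
    )
    pos_sdlog <- setNames(rep(0.25, 8), names(pos_mean))

    sig <- pattern_intensity(design_row$sigm_pattern)
    pos_mean["sIgM"] <- sig$mean
    pos_sdlog["sIgM"] <- sig$sdlog

    p200 <- pct["CD200"] / 100
    r <- rbounded(1, design_row$mfir_lo, design_row$mfir_med, design_row$mfir_hi)
    # lowest ratio reachable with the positive-mean floor of 20
    r_lo <- (1 - p200) + p200 * 20 / iso$mean
    r <- max(r, r_lo)
    pos_mean["CD200"] <- max(20, iso$mean * (r - (1 - p200)) / p200)
    pos_sdlog["CD200"] <- 0.25

    tibble(
      sample_id = design_row$sample_id, diagnosis = design_row$diagnosis,
      subtype = design_row$subtype, marker = panel_markers(),
      pct_target = unname(pct[panel_markers()]),
      pos_mean = unname(pos_mean[panel_markers()]),
      pos_sdlog = unname(pos_sdlog[panel_markers()]),
      iso_mean = iso$mean, sigm_pattern = design_row$sigm_pattern,
      cd200_mfir_target = r, b_frac = design_row$b_frac
    )
  })
}

rbounded1 <- function(triple) rbounded(1, triple[1], triple[2], triple[3])

#' Draw marker profiles for a whole cohort design
#'
#' Applies [sample_patient_profile()] to every design row, using a
#' deterministic per-sample substream of `master_seed` so any single patient
#' can be regenerated in isolation.
#'
#' @param design A [cohort_design()] tibble.
#' @param master_seed Integer master seed.
#' @return A tidy tibble, one row per sample and marker.
#' @export
#' @examples
#' d <- cohort_design(c(MCL = 2))
#' pr <- sample_profiles(d, master_seed = 42)
#' dplyr::filter(pr, marker == "CD200")
sample_profiles <- function(design, master_seed = 1L) {
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    sample_patient_profile(design[i, ],
                           seed = substream_seed(master_seed, design$seed_offset[i], 1L))
  })
}
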