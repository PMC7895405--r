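# Cohort composition and per-case design "cards".
#
# The generator is card-based: each card fixes, for one stratum of patients,
# which markers score a point (favourable pattern), the sIgM intensity class,
# and the support (lo, median, hi) of the CD200 percent-positive and MFIR
# target distributions. Numeric targets are later drawn inside those supports,
# always >= 5 percentage points away from the 30% decision boundary, so the
# classification counts the cards encode are stable across seeds.

#' Default cohort composition
#'
#' Counts per diagnostic subtype for the default simulated cohort of 252
#' B-cell chronic lymphoproliferative disorder (B-CLPD) cases: 199 CLL
#' (189 typical + 10 atypical), 20 mantle cell lymphoma (MCL), 17 marginal
#' zone lymphoma (MZL), 8 hairy cell leukemia (HCL), 3 follicular lymphoma
#' (FL) and 5 other B-CLPD (lymphoplasmacytic lymphoma, Waldenstrom
#' macroglobulinemia, prolymphocytic leukemia).
#'
#' @return Named integer vector of case counts per subtype.
#' @export
#' @examples
#' cohort_composition()
cohort_composition <- function() {
  c("CLL-typical" = 189L, "CLL-atypical" = 10L, "MCL" = 20L, "MZL" = 17L,
    "HCL" = 8L, "FL" = 3L, "OTHER" = 5L)
}

#' Diagnosis case cards: the generative template set
#'
#' One row per design stratum. `pt_*` columns give the marker point the
#' stratum is built to attain under the scoring rules (CD5/CD23/CD200 point 1
#' iff percent-positive >= 30; FMC7/CD79b point 1 iff < 30; sIgM point 1 iff
#' the expression pattern is weak). `cd200_lo/med/hi` bound the CD200
#' percent-positive target; `mfir_lo/med/hi` bound the CD200 MFIR target.
#'
#' Cards encode the designed study conditions: all CLL cards are CD200
#' positive (typical support 88.9-100%, atypical 50.6-84.7%); MCL CD200
#' support is capped at 25% so no MCL case can cross the 30% cutoff; exactly
#' one HCL card (classical score 3, CD200 positive) reaches the augmented
#' score of 4; two MZL and two PLL cards reach 3 points on the four-marker
#' score.
#'
#' @return A tibble with one row per card.
#' @export
#' @examples
#' dplyr::count(case_cards(), subtype, wt = n_default)
case_cards <- function() {
  card <- function(id, subtype, n, cd5, cd23, fmc7, cd79b, sigm_pattern,
                   cd200, cd200_sup, mfir_sup, b_frac) {
    tibble(
      card_id = id, subtype = subtype, n_default = as.integer(n),
      pt_CD5 = cd5, pt_CD23 = cd23, pt_FMC7 = fmc7, pt_CD79b = cd79b,
      pt_sIgM = as.integer(sigm_pattern == "weak"), pt_CD200 = cd200,
      sigm_pattern = sigm_pattern,
      cd200_lo = cd200_sup[1], cd200_med = cd200_sup[2], cd200_hi = cd200_sup[3],
      mfir_lo = mfir_sup[1], mfir_med = mfir_sup[2], mfir_hi = mfir_sup[3],
      b_frac = b_frac
    )
  }
  # CD200 supports per subtype (percent-positive lo/med/hi)
  cll_t  <- c(88.9, 98.0, 100)   # typical CLL: uniformly strong CD200
  cll_a  <- c(50.6, 62.6, 84.7)  # atypical CLL: positive but dimmer
  neg    <- function(lo, med = 5) c(lo, med, 25)  # CD200-negative: capped at 25
  # CD200 MFIR supports; positives >= 20 (above the 18 cutoff), negatives <= 15
  m_cll_t <- c(39.3, 59.0, 69.9)
  m_cll_a <- c(40.0, 50.3, 57.0)
  m_neg   <- c(1.2, 3.3, 15.0)
  bind_rows(
    # CLL: classical 94 @5 / 95 @4 / (atypical) 10 @3; four-marker 187 @4, 12 @3
    card("cll_t5",        "CLL-typical", 94, 1, 1, 1, 1, "weak", 1, cll_t, m_cll_t, 0.85),
    card("cll_t4_fmc7",   "CLL-typical", 47, 1, 1, 0, 1, "weak", 1, cll_t, m_cll_t, 0.85),
    card("cll_t4_cd79b",  "CLL-typical", 46, 1, 1, 1, 0, "weak", 1, cll_t, m_cll_t, 0.85),
    card("cll_t4_cd23",   "CLL-typical",  2, 1, 0, 1, 1, "weak", 1, cll_t, m_cll_t, 0.85),
    card("cll_a_cd23_fmc7",  "CLL-atypical", 5, 1, 0, 0, 1, "weak",     1, cll_a, m_cll_a, 0.85),
    card("cll_a_sigm_cd79b", "CLL-atypical", 5, 1, 1, 1, 0, "moderate", 1, cll_a, m_cll_a, 0.85),
    # MCL: CD5+, CD200 support strictly below 30; classical 1(10), 2(7), 3(3)
    card("mcl_1", "MCL", 10, 1, 0, 0, 0, "strong", 0, c(0.1, 2.3, 25), m_neg, 0.70),
    card("mcl_2", "MCL",  7, 1, 0, 0, 1, "strong", 0, c(0.1, 2.3, 25), m_neg, 0.70),
    card("mcl_3", "MCL",  3, 1, 0, 1, 1, "strong", 0, c(0.1, 2.3, 25), m_neg, 0.70),
    # HCL: classical 0(1), 1(3), 2(3), 3(1); 5/8 CD200+; one augmented-4 case
    card("hcl_0_neg", "HCL", 1, 0, 0, 0, 0, "strong",   0, neg(0.9), m_neg, 0.60),
    card("hcl_1_pos", "HCL", 2, 0, 0, 1, 0, "strong",   1, c(35, 50, 91.8), c(20, 46.5, 70), 0.60),
    card("hcl_1_neg", "HCL", 1, 0, 0, 0, 1, "moderate", 0, neg(0.9), m_neg, 0.60),
    card("hcl_2_pos", "HCL", 2, 0, 0, 1, 1, "strong",   1, c(35, 50, 91.8), c(20, 46.5, 70), 0.60),
    card("hcl_2_neg", "HCL", 1, 0, 0, 1, 1, "moderate", 0, neg(0.9), m_neg, 0.60),
    card("hcl_3_pos", "HCL", 1, 0, 0, 1, 1, "weak",     1, c(35, 50, 91.8), c(20, 46.5, 70), 0.60),
    # MZL: classical 0(7), 1(4), 2(4), 3(2); 12/17 CD200+
    card("mzl_0_pos",    "MZL", 4, 0, 0, 0, 0, "moderate", 1, c(35, 55.9, 88), c(20, 24, 58), 0.65),
    card("mzl_0_neg",    "MZL", 3, 0, 0, 0, 0, "moderate", 0, neg(0.4), m_neg, 0.65),
    card("mzl_1_pos",    "MZL", 4, 0, 0, 1, 0, "moderate", 1, c(35, 55.9, 88), c(20, 24, 58), 0.65),
    card("mzl_2_pos_4m", "MZL", 2, 0, 1, 0, 0, "weak",     1, c(35, 55.9, 88), c(20, 24, 58), 0.65),
    card("mzl_2_pos",    "MZL", 2, 0, 0, 1, 1, "moderate", 1, c(35, 55.9, 88), c(20, 24, 58), 0.65),
    card("mzl_3_neg",    "MZL", 2, 0, 0, 1, 1, "weak",     0, neg(0.4), m_neg, 0.65),
    # FL: classical 2(2), 3(1); 1/3 CD200+
    card("fl_2_pos", "FL", 1, 0, 1, 1, 0, "moderate", 1, c(35, 55, 70.6), c(20, 35, 43), 0.60),
    card("fl_2_neg", "FL", 1, 0, 0, 1, 1, "strong",   0, neg(0.9, 3), m_neg, 0.60),
    card("fl_3_neg", "FL", 1, 0, 1, 1, 1, "moderate", 0, neg(0.9, 3), m_neg, 0.60),
    # Other B-CLPD (2 LPL, 1 WM, 2 PLL): classical 0(1), 1(1), 2(3); 2/5 CD200+
    card("oth_lpl_0", "OTHER", 1, 0, 0, 0, 0, "strong",   0, neg(1.9, 6), m_neg, 0.60),
    card("oth_wm_1",  "OTHER", 1, 0, 0, 0, 1, "strong",   0, neg(1.9, 6), m_neg, 0.60),
    card("oth_lpl_2", "OTHER", 1, 0, 0, 1, 1, "moderate", 0, neg(1.9, 6), m_neg, 0.60),
    card("oth_pll_2", "OTHER", 2, 0, 1, 0, 0, "weak",     1, c(35, 46, 57.6), c(20, 32, 45), 0.60)
  )
}

diagnosis_group <- function(subtype) {
  ifelse(subtype %in% c("CLL-typical", "CLL-atypical"), "CLL", subtype)
}

#' Validate the case-card template set
#'
#' Checks the structural invariants the downstream analysis relies on:
#' CD200 supports ordered and inside \[0, 100\]; CLL cards CD200-positive with
#' support inside \[50.6, 100\] and CD5 support above 30; MCL CD200 support
#' strictly below 30; sIgM point consistent with the pattern class; positive
#' cards' MFIR support at or above 20 and negative cards' at or below 15.
#'
#' @param cards A tibble as returned by [case_cards()].
#' @return Invisibly `TRUE`; aborts with a message on the first violation.
#' @export
validate_case_cards <- function(cards = case_cards()) {
  stopifnot(nrow(cards) > 0)
  ok <- function(cond, msg) if (!all(cond)) abort(paste("case card invariant violated:", msg))
  ok(cards$cd200_lo <= cards$cd200_med & cards$cd200_med <= cards$cd200_hi,
     "CD200 support must be ordered lo <= med <= hi")
  ok(cards$cd200_lo >= 0 & cards$cd200_hi <= 100, "CD200 support must lie in [0, 100]")
  ok(cards$mfir_lo <= cards$mfir_med & cards$mfir_med <= cards$mfir_hi,
     "MFIR support must be ordered")
  ok(cards$pt_sIgM == as.integer(cards$sigm_pattern == "weak"),
     "sIgM point must equal (pattern == weak)")
  cll <- cards$subtype %in% c("CLL-typical", "CLL-atypical")
  ok(cards$pt_CD200[cll] == 1L & cards$cd200_lo[cll] >= 50.6,
     "CLL cards must be CD200-positive with support in [50.6, 100]")
  ok(cards$pt_CD5[cll] == 1L, "CLL cards must carry the CD5 point")
  mcl <- cards$subtype == "MCL"
  ok(cards$pt_CD200[mcl] == 0L & cards$cd200_hi[mcl] < 30,
     "MCL CD200 support must be strictly below 30")
  # off-boundary margin: positives start >= 35, negatives end <= 25
  ok(cards$cd200_lo[cards$pt_CD200 == 1L] >= 35 | cll[cards$pt_CD200 == 1L],
     "CD200-positive supports must start >= 5 points above the 30% boundary")
  ok(cards$cd200_hi[cards$pt_CD200 == 0L] <= 25,
     "CD200-negative supports must end >= 5 points below the 30% boundary")
  ok(cards$mfir_lo[cards$pt_CD200 == 1L] >= 20, "CD200-positive MFIR support must be >= 20")
  ok(cards$mfir_hi[cards$pt_CD200 == 0L] <= 15, "CD200-negative MFIR support must be <= 15")
  ok(cards$b_frac > 0 & cards$b_frac <= 1, "B-cell fraction must lie in (0, 1]")
  invisible(TRUE)
}

#' Expand the card set into a per-sample cohort design
#'
#' Builds one row per patient by replicating each subtype's cards to the
#' requested composition. With the default composition the design is exactly
#' the card counts; a custom composition recycles that subtype's card
#' sequence. Specimen types are assigned so that peripheral blood and bone
#' marrow appear in the 195:57 ratio of the emulated cohort.
#'
#' @param composition Named integer vector of counts per subtype
#'   (default [cohort_composition()]).
#' @param seed Integer seed controlling the specimen-type assignment.
#' @param cards Card set, validated with [validate_case_cards()].
#' @return A tibble with columns `sample_id`, `diagnosis`, `subtype`,
#'   `card_id`, `specimen_type`, `seed_offset` plus the card's design columns.
#' @export
#' @examples
#' d <- cohort_design(c("CLL-typical" = 2, MCL = 1))
#' d[, c("sample_id", "subtype", "card_id", "specimen_type")]
cohort_design <- function(composition = cohort_composition(), seed = 1L,
                          cards = case_cards()) {
  validate_case_cards(cards)
  composition <- composition[composition > 0]
  if (length(composition) == 0) {
    return(tibble(sample_id = character(), diagnosis = character(),
                  subtype = character(), card_id = character(),
                  specimen_type = character(), seed_offset = integer()))
  }
  unknown <- setdiff(names(composition), unique(cards$subtype))
  if (length(unknown) > 0) {
    abort(paste("unknown subtype(s) in composition:", paste(unknown, collapse = ", ")))
  }
  rows <- purrr::imap(as.list(composition), function(k, subtype) {
    sub <- cards[cards$subtype == subtype, , drop = FALSE]
    seq_default <- rep(seq_len(nrow(sub)), times = sub$n_default)
    idx <- head(rep(seq_default, length.out = max(k, 0) + length(seq_default)), k)
    sub[idx, , drop = FALSE]
  })
  design <- bind_rows(rows)
  n <- nrow(design)
  n_bm <- round(n * 57 / 252)
  bm_idx <- with_local_seed(seed, sample.int(n, n_bm))
  design %>%
    mutate(
      sample_id = sprintf("S%03d", row_number()),
      diagnosis = diagnosis_group(.data$subtype),
      specimen_type = ifelse(row_number() %in% bm_idx, "BM", "PB"),
      seed_offset = row_number()
    ) %>%
    select("sample_id", "diagnosis", "subtype", "card_id", "specimen_type",
           "seed_offset", dplyr::everything(), -"n_default")
}

# Run `expr` under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-sample substream seed derived from the master seed, the
# sample index and a stage stream id; stays below 2^31 and avoids
# double-precision overflow.
substream_seed <- function(master_seed, index, stream = 0L) {
  h <- (as.numeric(master_seed) %% 1e6) * 69069 +
    (as.numeric(index) %% 1e6) * 1013904223 +
    (as.numeric(stream) %% 1e3) * 60493 + 97
  as.integer(h %% 2147483629)
}
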