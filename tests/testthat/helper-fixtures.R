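# Shared small fixtures, built once per test run.

# One typical-CLL and one MCL sample at modest event counts: enough B cells
# (~2000) for stable percents while keeping the suite fast.
fix_design <- cohort_design()
fix_cll <- simulate_sample(fix_design[1, ], master_seed = 101,
                           n_events = 6000, n_isotype = 2500)
fix_cll_res <- analyze_sample(fix_cll$events, fix_cll$isotype, sample_id = "S001")
fix_mcl_row <- fix_design[fix_design$subtype == "MCL", ][1, ]
fix_mcl <- simulate_sample(fix_mcl_row, master_seed = 101,
                           n_events = 6000, n_isotype = 2500)

# Hand-built one-sample quantification table for scoring tests.
make_results <- function(cd5 = 95, cd23 = 80, fmc7 = 10, cd79b = 20,
                         sigm_pattern = "weak", cd200 = 98, cd200_mfir = 59) {
  tibble::tibble(
    marker = c("CD5", "CD23", "FMC7", "CD79b", "sIgM", "CD200"),
    percent_positive = c(cd5, cd23, fmc7, cd79b, 90, cd200),
    mfir = c(40, 30, 2, 3, 5, cd200_mfir),
    pattern = c("strong", "strong", "strong", "strong", sigm_pattern, "strong"),
    n_lymphocytes = 4000L, n_b_cells = 3000L
  )
}

# A design row whose numeric supports are all point masses, for determinism
# and degenerate-template tests.
point_mass_row <- function() {
  row <- cohort_design(c("CLL-typical" = 1))[1, ]
  row$cd200_lo <- row$cd200_med <- row$cd200_hi <- 97.9
  row$mfir_lo <- row$mfir_med <- row$mfir_hi <- 59
  row
}
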