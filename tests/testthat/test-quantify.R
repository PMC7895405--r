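test_that("percent_positive matches a direct counting oracle", {
  iso <- as.numeric(1:1000)           # threshold 995.5
  marker <- c(rep(10, 140), rep(2000, 60))
  expect_equal(percent_positive(marker, iso), 30)   # 60 of 200 above
  expect_equal(percent_positive(rep(2000, 7), iso), 100)
  # marker drawn from the isotype distribution: ~ the 0.5% complement
  set.seed(7)
  x <- rlnorm(20000, 1, 0.5)
  expect_lt(abs(percent_positive(x, x) - 0.5), 0.2)
  expect_error(percent_positive(numeric(0), iso), "no B-cell events")
})

test_that("percent_positive is invariant under joint monotone rescaling", {
  set.seed(31)
  for (i in 1:20) {
    iso <- rlnorm(300, 1, 0.6)
    marker <- c(rlnorm(200, 1, 0.6), rlnorm(100, 5, 0.4))
    base <- percent_positive(marker, iso)
    for (f in list(function(x) 3.7 * x + 2,
                   function(x) x^2,
                   function(x) log1p(x))) {
      expect_equal(percent_positive(f(marker), f(iso)), base)
    }
  }
})

test_that("mfir matches direct arithmetic and is scale invariant", {
  expect_equal(mfir(rep(5, 10), rep(5, 10)), 1)
  expect_equal(mfir(c(40, 60), c(1, 3)), 25)       # mean 50 / mean 2
  set.seed(8)
  x <- rlnorm(500, 3, 1); y <- rlnorm(500, 1, 1)
  expect_equal(mfir(7.3 * x, 7.3 * y), mfir(x, y))
  expect_equal(mfir(x, y, stat = "median"), median(x) / median(y))
  expect_error(mfir(x, rep(0, 5)), "positive")
  expect_error(mfir(numeric(0), y), "non-empty")
})

test_that("expression pattern classifies by log decade of the positive median", {
  expect_equal(expression_pattern(rep(5, 11)), "weak")
  expect_equal(expression_pattern(rep(50, 11)), "moderate")
  expect_equal(expression_pattern(rep(500, 11)), "strong")
  expect_equal(expression_pattern(c(9.9, 9.9, 9.9)), "weak")
  expect_equal(expression_pattern(c(10, 10, 10)), "moderate")
  empty <- expression_pattern(numeric(0))
  expect_equal(as.character(empty), "weak")
  expect_true(attr(empty, "flagged"))
})

test_that("analyze_sample agrees with a brute-force recomputation", {
  # naive oracle: loops over events, no package quantifiers
  pm <- point_mass_row()
  sim <- simulate_sample(pm, master_seed = 17, n_events = 1000, n_isotype = 800)
  res <- suppressWarnings(
    analyze_sample(sim$events, sim$isotype, sample_id = "bf"))
  gd <- gate_defaults()
  keep <- function(tab) {
    out <- tab[0, ]
    for (i in seq_len(nrow(tab))) {
      if (tab$CD45[i] >= gd$cd45_min && tab$SSC[i] <= gd$ssc_max) {
        out <- rbind(out, tab[i, ])
      }
    }
    out
  }
  lym <- keep(as.data.frame(sim$events))
  lym_iso <- keep(as.data.frame(sim$isotype))
  thr_of <- function(v) {
    v <- sort(v); h <- length(v) * 0.995 + 0.5
    v[floor(h)] + (h - floor(h)) * (v[min(floor(h) + 1, length(v))] - v[floor(h)])
  }
  b <- lym[lym$CD19 > thr_of(lym_iso$CD19), ]
  for (m in panel_markers()) {
    thr <- thr_of(lym_iso[[m]])
    n_above <- 0
    for (v in b[[m]]) if (v > thr) n_above <- n_above + 1
    row <- res[res$marker == m, ]
    expect_equal(row$percent_positive, 100 * n_above / nrow(b))
    expect_equal(row$mfir, mean(b[[m]]) / mean(lym_iso[[m]]))
    expect_equal(row$n_b_cells, nrow(b))
    expect_equal(row$n_lymphocytes, nrow(lym))
  }
})

test_that("analyze_sample surfaces structural errors with the sample id", {
  debris <- tibble::as_tibble(
    lapply(setNames(nm = event_columns()), function(x) runif(300, 0, 3)))
  ok_iso <- fix_cll$isotype
  expect_error(suppressWarnings(analyze_sample(debris, ok_iso, sample_id = "SX")),
               "SX.*empty lymphocyte gate")
  expect_error(analyze_sample(fix_cll$events[, 1:4], ok_iso, sample_id = "SY"),
               "SY.*lacks column")
})

test_that("whole-sample quantification hits the designed CLL and MCL patterns", {
  cd200 <- fix_cll_res[fix_cll_res$marker == "CD200", ]
  expect_gte(cd200$percent_positive, 30)
  expect_gte(cd200$mfir, 18)
  res_m <- analyze_sample(fix_mcl$events, fix_mcl$isotype, sample_id = "mcl")
  expect_lt(res_m$percent_positive[res_m$marker == "CD200"], 30)
  expect_lt(res_m$mfir[res_m$marker == "CD200"], 18)
  expect_equal(fix_cll_res$pattern[fix_cll_res$marker == "sIgM"], "weak")
  expect_equal(res_m$pattern[res_m$marker == "sIgM"], "strong")
})
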