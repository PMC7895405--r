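test_that("confusion counts are standard 2x2 with CLL positive", {
  expect_equal(confusion_counts(c(TRUE, FALSE), c(TRUE, FALSE)),
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  # cohort classical distribution at the >= 4 screen
  calls <- rep(c(TRUE, FALSE, FALSE), c(189, 10, 53))
  truth <- rep(c(TRUE, FALSE), c(199, 53))
  cm <- confusion_counts(calls, truth)
  expect_equal(unlist(cm), c(tp = 189L, fp = 0L, fn = 10L, tn = 53L))
  all_pos <- confusion_counts(rep(TRUE, 252), truth)
  expect_equal(all_pos$tn, 0L)
  expect_equal(all_pos$fp, 53L)
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("Clopper-Pearson intervals match the closed forms and binom.test", {
  ci <- proportion_ci(189, 199)
  expect_equal(round(100 * ci$point, 2), 94.97)
  expect_equal(round(100 * ci$lower, 1), 91.0)
  expect_equal(round(100 * ci$upper, 1), 97.6)
  expect_equal(proportion_ci(0, 10)$point, 0)
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(53, 53)$lower, 0.025^(1 / 53))
  expect_equal(proportion_ci(53, 53)$upper, 1)
  # cross-check against the independent exact-test implementation
  for (x in c(0, 1, 5, 26, 52, 53)) {
    bt <- stats::binom.test(x, 53)$conf.int
    ci <- proportion_ci(x, 53)
    expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
  }
  expect_error(proportion_ci(5, 0), "at least 1")
  expect_error(proportion_ci(9, 5), "successes")
})

test_that("exact interval keeps nominal coverage at n = 53, p = 0.9", {
  set.seed(1234)
  n <- 53; p <- 0.9
  x <- rbinom(2000, n, p)
  covered <- vapply(x, function(k) {
    ci <- proportion_ci(k, n)
    ci$lower <= p && p <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  brute <- function(s, t) {
    pos <- s[t]; neg <- s[!t]; tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(55)
  for (i in 1:15) {
    n <- sample(10:120, 1)
    t <- c(TRUE, FALSE, runif(n - 2) < 0.5)   # both classes guaranteed
    s <- sample(0:6, n, replace = TRUE)       # heavy ties, ordinal scores
    expect_equal(rank_auc(s, t), brute(s, t))
  }
  expect_equal(rank_auc(c(5, 5, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rank_auc(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(rank_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("rank AUC and DeLong interval agree with pROC", {
  set.seed(19)
  s <- c(rnorm(60, 1), rnorm(40))
  t <- rep(c(TRUE, FALSE), c(60, 40))
  proc_auc <- as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE, direction = "<")))
  expect_equal(rank_auc(s, t), proc_auc, tolerance = 1e-12)
  dl <- auc_ci_delong(s, t)
  proc_ci <- as.numeric(pROC::ci.auc(pROC::roc(t, s, quiet = TRUE, direction = "<"),
                                     method = "delong"))
  expect_equal(c(dl$lower, dl$auc, dl$upper), proc_ci, tolerance = 1e-6)
})

test_that("Youden-optimal cutoff matches an exhaustive scan and its operating point", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(30:150, 1)
    t <- c(TRUE, FALSE, runif(n - 2) < 0.6)
    v <- round(ifelse(t, rnorm(n, 60, 25), rnorm(n, 30, 25)), 1)
    out <- roc_optimal_cutoff(v, t)
    # oracle: scan every observed value as a threshold
    js <- vapply(sort(unique(v)), function(th) {
      mean(v[t] >= th) + mean(v[!t] < th) - 1
    }, numeric(1))
    expect_equal(out$youden_j, max(js))
    # reported sens/spec reproduce independently at the returned threshold
    expect_equal(out$sensitivity, mean(v[t] >= out$cutoff))
    expect_equal(out$specificity, mean(v[!t] < out$cutoff))
  }
  # fully separated clusters: the smallest positive value is returned
  sep <- roc_optimal_cutoff(c(10, 11, 12, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$cutoff, 10)
  expect_equal(sep$youden_j, 1)
  # single achievable threshold
  one <- roc_optimal_cutoff(rep(4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(one$cutoff, 4)
})

test_that("optimal CD200 cutoff on profile targets separates CLL from non-CLL", {
  d <- cohort_design()
  pr <- sample_profiles(d, master_seed = 13)
  cd200 <- pr[pr$marker == "CD200", ]
  out <- roc_optimal_cutoff(cd200$pct_target, cd200$diagnosis == "CLL")
  expect_gt(out$cutoff, 30)
  expect_lt(out$cutoff, 100)
  expect_gt(out$youden_j, 0.5)
  mw <- mann_whitney(cd200$pct_target[cd200$diagnosis == "CLL"],
                     cd200$pct_target[cd200$diagnosis != "CLL"])
  expect_lt(mw$p_value, 1e-4)
})

test_that("McNemar uses the exact branch then the corrected chi-square", {
  same <- rep(TRUE, 8)
  expect_equal(mcnemar_test(same, same, same)$p_value, 1)
  ex <- mcnemar_test(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(ex$method, "exact")
  expect_equal(ex$p_value, 2 * 0.5^10)
  truth <- rep(TRUE, 100)
  a <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 60))
  b <- c(rep(FALSE, 30), rep(TRUE, 10), rep(TRUE, 60))
  cs <- mcnemar_test(a, b, truth)
  expect_equal(cs$statistic, (abs(30 - 10) - 1)^2 / 40)   # 9.025
  expect_equal(cs$p_value, stats::pchisq(9.025, 1, lower.tail = FALSE))
  expect_error(mcnemar_test(a, b, truth[1:10]), "equal length")
})

test_that("Mann-Whitney switches between exact and tie-corrected branches", {
  ex <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$u, 0)
  expect_equal(ex$p_value, 0.1)   # enumeration over all 20 arrangements
  id <- mann_whitney(1:10, 1:10)
  expect_equal(id$u, 100 / 2)
  expect_gt(id$p_value, 0.99)
  big <- mann_whitney(rnorm(50), rnorm(60, 2))
  expect_lt(big$p_value, 1e-6)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("evaluate_accuracy composes counts, intervals and AUCs coherently", {
  scores <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:252),
    classical_score = rep(c(5, 4, 3, 3, 2, 1, 0), c(94, 95, 10, 7, 19, 18, 9)),
    augmented_score = rep(c(6, 5, 4, 3, 3, 2, 1, 1, 0), c(94, 95, 10, 6, 9, 16, 12, 4, 6)),
    four_marker_score = rep(c(4, 3, 3, 2, 1, 0), c(187, 12, 4, 10, 30, 9)))
  truth <- rep(c(TRUE, FALSE), c(199, 53))
  acc <- evaluate_accuracy(scores, truth)
  sys <- acc$systems
  cl <- sys[sys$system == "classical", ]
  expect_equal(cl$sensitivity, 189 / 199)
  expect_equal(cl$specificity, 1)
  expect_true(all(sys$sens_lower <= sys$sensitivity & sys$sensitivity <= sys$sens_upper))
  expect_true(all(sys$auc >= 0 & sys$auc <= 1))
  td <- tidy(acc)
  expect_setequal(unique(td$metric), c("sensitivity", "specificity", "overall", "auc"))
  expect_true(all(td$lower <= td$estimate & td$estimate <= td$upper))
  gl <- glance(acc)
  expect_equal(gl$n, 252L)
  expect_error(evaluate_accuracy(scores, rep(TRUE, 252)), "both CLL and non-CLL")
})
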