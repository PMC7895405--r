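# Diagnostic-accuracy evaluation: exact binomial intervals, tie-corrected
# rank AUC with DeLong intervals, Youden-optimal cutoffs, paired and
# unpaired tests.

#' Confusion counts for a binary CLL screen
#'
#' Standard 2x2 counts with CLL as the positive class.
#'
#' @param binary_calls Logical (or 0/1) vector of screen calls.
#' @param truth Logical (or 0/1) vector of true CLL status, same length.
#' @return A tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion_counts <- function(binary_calls, truth) {
  if (length(binary_calls) != length(truth)) {
    abort("calls and truth must have equal length")
  }
  calls <- as.logical(binary_calls); tr <- as.logical(truth)
  tibble(tp = sum(calls & tr), fp = sum(calls & !tr),
         fn = sum(!calls & tr), tn = sum(!calls & !tr))
}

#' Exact (Clopper-Pearson) binomial proportion with 95% CI
#'
#' Point estimate `successes / n` with the exact two-sided 95% interval from
#' the beta-quantile closed form: lower `qbeta(.025, x, n-x+1)` (0 when
#' `x = 0`), upper `qbeta(.975, x+1, n-x)` (1 when `x = n`). For `x = n` the
#' lower bound equals `0.025^(1/n)`.
#'
#' @param successes,n Non-negative integers, `successes <= n`, `n >= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `point`, `lower`, `upper`.
#' @export
#' @examples
#' proportion_ci(189, 199)
proportion_ci <- function(successes, n, conf_level = 0.95) {
  if (n < 1) abort("n must be at least 1")
  if (successes < 0 || successes > n) abort("successes must lie in [0, n]")
  a <- (1 - conf_level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  tibble(point = successes / n, lower = lower, upper = upper)
}

#' Tie-corrected rank AUC
#'
#' Probability that a random CLL sample outranks a random non-CLL sample,
#' with half credit for ties: `[#(pos > neg) + 0.5 * #ties] / (n_pos *
#' n_neg)`; the normalised Mann-Whitney statistic. Computed from midranks so
#' large inputs stay O(n log n).
#'
#' @param scores Numeric (or ordinal) score per sample.
#' @param truth Logical vector, `TRUE` for CLL; both classes must be present.
#' @return The AUC in \[0, 1\].
#' @export
#' @examples
#' rank_auc(c(5, 4, 4, 1, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE))
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("scores and truth must have equal length")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for a rank AUC
#'
#' Placement-based variance estimate: the AUC variance is
#' `var(V10)/n_pos + var(V01)/n_neg` where `V10`/`V01` are per-sample
#' placement values, giving a normal-theory interval truncated to \[0, 1\].
#'
#' @inheritParams rank_auc
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `auc`, `lower`, `upper`, `se`.
#' @export
auc_ci_delong <- function(scores, truth, conf_level = 0.95) {
  truth <- as.logical(truth)
  auc <- rank_auc(scores, truth)
  x <- scores[truth]; y <- scores[!truth]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
  v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
  se <- sqrt(var(v10) / length(x) + var(v01) / length(y))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(auc = auc, lower = max(0, auc - z * se),
         upper = min(1, auc + z * se), se = se)
}

#' Youden-optimal ROC cutoff
#'
#' Scans every achievable threshold (the decision rule is `value >= cutoff`
#' is a CLL call) and returns the cutoff maximising Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' sensitivity, then toward the lower cutoff. For fully separated classes
#' this returns the smallest positive-class value.
#'
#' @param values Continuous or ordinal marker values.
#' @param truth Logical vector, `TRUE` for CLL; both classes required.
#' @return A tibble with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
#' @examples
#' roc_optimal_cutoff(c(9, 8, 7, 2, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
roc_optimal_cutoff <- function(values, truth) {
  truth <- as.logical(truth)
  if (length(values) != length(truth)) abort("values and truth must have equal length")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  cand <- sort(unique(values))
  sens <- vapply(cand, function(t) sum(values[truth] >= t) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(values[!truth] < t) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-sens[best], cand[best])][1]
  tibble(cutoff = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best])
}

#' McNemar test between two paired diagnostic rules
#'
#' Per-sample correctness is derived against the truth; the test acts on the
#' discordant counts b (A correct, B wrong) and c (A wrong, B correct). With
#' `b + c <= 25` the exact two-sided binomial p-value `2 * P(X <= min(b, c))`
#' (capped at 1) is used; otherwise the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` on 1 df. `b + c = 0` gives p = 1.
#'
#' @param calls_A,calls_B Logical call vectors of the two rules.
#' @param truth Logical truth vector, same length.
#' @return A tibble with `b`, `c`, `statistic` (chi-square, `NA` for the
#'   exact branch), `p_value`, `method`.
#' @export
#' @examples
#' mcnemar_test(c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE))
mcnemar_test <- function(calls_A, calls_B, truth) {
  if (length(calls_A) != length(truth) || length(calls_B) != length(truth)) {
    abort("calls and truth must have equal length")
  }
  ok_a <- as.logical(calls_A) == as.logical(truth)
  ok_b <- as.logical(calls_B) == as.logical(truth)
  b <- sum(ok_a & !ok_b); cc <- sum(!ok_a & ok_b)
  n <- b + cc
  if (n == 0) {
    return(tibble(b = b, c = cc, statistic = NA_real_, p_value = 1, method = "exact"))
  }
  if (n <= 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    tibble(b = b, c = cc, statistic = NA_real_, p_value = p, method = "exact")
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    tibble(b = b, c = cc, statistic = stat,
           p_value = pchisq(stat, df = 1, lower.tail = FALSE),
           method = "chi-square with continuity correction")
  }
}

#' Mann-Whitney U test for two independent groups
#'
#' Two-sided; exact enumeration when both groups have at most 20 values and
#' there are no ties, otherwise the normal approximation with tie correction.
#'
#' @param group_1,group_2 Non-empty numeric vectors.
#' @return A tibble with `u` (the U statistic for `group_1`) and `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(group_1, group_2) {
  if (length(group_1) == 0 || length(group_2) == 0) {
    abort("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_1, group_2)) > 0
  exact <- length(group_1) <= 20 && length(group_2) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(group_1, group_2, exact = exact))
  tibble(u = unname(wt$statistic), p_value = wt$p.value)
}

#' Evaluate the diagnostic accuracy of the scoring systems
#'
#' Computes, for each of the three systems, the 2x2 confusion at the
#' score >= 4 screen, exact sensitivity/specificity/overall-proportion
#' intervals, the tie-corrected rank AUC of the full score with a DeLong
#' interval, and McNemar comparisons of the augmented and four-marker
#' systems against the classical score.
#'
#' @param scores Output of [score_cohort()].
#' @param truth Logical vector (or manifest tibble with `sample_id` and
#'   `diagnosis`, matched by `sample_id`): `TRUE`/"CLL" marks true CLL.
#' @return An object of class `cllscore_accuracy`: a list with tibbles
#'   `systems`, `mcnemar`, and counts `n_cll`, `n_non_cll`. Methods:
#'   [tidy()], [glance()], `print()`, [autoplot()].
#' @export
evaluate_accuracy <- function(scores, truth) {
  if (is.data.frame(truth)) {
    truth <- truth$diagnosis[match(scores$sample_id, truth$sample_id)] == "CLL"
  }
  truth <- as.logical(truth)
  if (length(truth) != nrow(scores) || anyNA(truth)) {
    abort("truth must give one CLL status per scored sample")
  }
  if (!any(truth) || all(truth)) {
    abort("accuracy evaluation needs both CLL and non-CLL samples")
  }
  systems <- tibble(
    system = c("classical", "augmented", "four_marker"),
    col = c("classical_score", "augmented_score", "four_marker_score")
  )
  sys_tbl <- purrr::map_dfr(seq_len(nrow(systems)), function(i) {
    sc <- scores[[systems$col[i]]]
    calls <- sc >= 4
    cm <- confusion_counts(calls, truth)
    se <- proportion_ci(cm$tp, cm$tp + cm$fn)
    sp <- proportion_ci(cm$tn, cm$tn + cm$fp)
    ov <- proportion_ci(cm$tp + cm$tn, nrow(scores))
    au <- auc_ci_delong(sc, truth)
    tibble(system = systems$system[i], cm,
           sensitivity = se$point, sens_lower = se$lower, sens_upper = se$upper,
           specificity = sp$point, spec_lower = sp$lower, spec_upper = sp$upper,
           overall = ov$point, overall_lower = ov$lower, overall_upper = ov$upper,
           auc = au$auc, auc_lower = au$lower, auc_upper = au$upper)
  })
  calls_of <- function(col) scores[[col]] >= 4
  mcn <- bind_rows(
    mutate(mcnemar_test(calls_of("classical_score"), calls_of("augmented_score"), truth),
           comparison = "classical vs augmented", .before = 1),
    mutate(mcnemar_test(calls_of("classical_score"), calls_of("four_marker_score"), truth),
           comparison = "classical vs four_marker", .before = 1)
  )
  structure(list(systems = sys_tbl, mcnemar = mcn,
                 n_cll = sum(truth), n_non_cll = sum(!truth)),
            class = "cllscore_accuracy")
}

#' @export
print.cllscore_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy: %d CLL vs %d non-CLL (screen: score >= 4)\n",
              x$n_cll, x$n_non_cll))
  print(as.data.frame(x$systems[, c("system", "sensitivity", "specificity", "auc")]),
        digits = 4, row.names = FALSE)
  cat("McNemar vs classical:\n")
  print(as.data.frame(x$mcnemar[, c("comparison", "b", "c", "p_value")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname evaluate_accuracy
#' @param x A `cllscore_accuracy` object.
#' @param ... Unused.
#' @export
tidy.cllscore_accuracy <- function(x, ...) {
  x$systems %>%
    tidyr::pivot_longer(
      cols = c("sensitivity", "specificity", "overall", "auc"),
      names_to = "metric", values_to = "estimate") %>%
    mutate(
      lower = dplyr::case_when(
        .data$metric == "sensitivity" ~ .data$sens_lower,
        .data$metric == "specificity" ~ .data$spec_lower,
        .data$metric == "overall" ~ .data$overall_lower,
        TRUE ~ .data$auc_lower),
      upper = dplyr::case_when(
        .data$metric == "sensitivity" ~ .data$sens_upper,
        .data$metric == "specificity" ~ .data$spec_upper,
        .data$metric == "overall" ~ .data$overall_upper,
        TRUE ~ .data$auc_upper)) %>%
    select("system", "metric", "estimate", "lower", "upper")
}

#' @rdname evaluate_accuracy
#' @export
glance.cllscore_accuracy <- function(x, ...) {
  best <- x$systems$system[which.max(x$systems$auc)]
  tibble(n = x$n_cll + x$n_non_cll, n_cll = x$n_cll, n_non_cll = x$n_non_cll,
         best_system = best, best_auc = max(x$systems$auc))
}
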