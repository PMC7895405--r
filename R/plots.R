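# ggplot2 figures for the result types.

#' CD200 expression by diagnosis
#'
#' Box/jitter plot of CD200 percent-positive and MFIR per diagnostic
#' subtype, the usual way heterogeneous CD200 expression across B-CLPD is
#' displayed. Dashed lines mark the decision cutoffs (30% and MFIR 18).
#'
#' @param results Output of [analyze_cohort()].
#' @param manifest Cohort manifest with `sample_id` and `subtype`.
#' @return A ggplot object.
#' @export
plot_cd200_distribution <- function(results, manifest) {
  df <- results %>%
    filter(.data$marker == "CD200") %>%
    left_join(select(manifest, "sample_id", "subtype"), by = "sample_id") %>%
    tidyr::pivot_longer(cols = c("percent_positive", "mfir"),
                        names_to = "measure", values_to = "value") %>%
    mutate(measure = dplyr::recode(.data$measure,
                                   percent_positive = "CD200 % positive",
                                   mfir = "CD200 MFIR"))
  cutoffs <- tibble(measure = c("CD200 % positive", "CD200 MFIR"),
                    cut = c(30, 18))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(data = cutoffs, ggplot2::aes(yintercept = .data$cut),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Score distributions per system
#'
#' Bar chart of the three score systems' distributions, CLL vs non-CLL, with
#' the score >= 4 diagnostic cutoff marked.
#'
#' @param scores Output of [score_cohort()].
#' @param manifest Cohort manifest with `sample_id` and `diagnosis`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, manifest) {
  df <- scores %>%
    left_join(select(manifest, "sample_id", "diagnosis"), by = "sample_id") %>%
    mutate(group = ifelse(.data$diagnosis == "CLL", "CLL", "non-CLL")) %>%
    tidyr::pivot_longer(cols = c("classical_score", "augmented_score", "four_marker_score"),
                        names_to = "system", values_to = "score") %>%
    mutate(system = sub("_score$", "", .data$system))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::geom_vline(xintercept = 3.5, linetype = "dashed") +
    ggplot2::facet_wrap(~system, scales = "free_x") +
    ggplot2::labs(x = "score", y = "patients", fill = NULL) +
    ggplot2::theme_bw()
}

#' @rdname evaluate_accuracy
#' @param object A `cllscore_accuracy` object.
#' @export
autoplot.cllscore_accuracy <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$system, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)") +
    ggplot2::theme_bw()
}
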