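# Pipeline orchestration: simulate -> analyze -> score -> evaluate -> report,
# every stage reading/writing a fixed CSV contract so stages are
# independently runnable (and the thin CLI in inst/cli can drive them).

#' Build a run configuration
#'
#' @param composition Named counts per subtype (default [cohort_composition()]).
#' @param events_per_sample Stained-tube events per sample (default 20000).
#' @param isotype_events Isotype-tube events per sample (default 5000).
#' @param master_seed Integer master seed; all randomness flows from it.
#' @param gate Lymphocyte gate thresholds, list with `cd45_min`, `ssc_max`.
#' @param positivity_percentile Isotype percentile for the positivity cut.
#' @param cd200_mode CD200 scoring mode, `"percent"` or `"mfir"`.
#' @param mfir_stat MFI statistic, `"mean"` (default) or `"median"`.
#' @param outdir Output directory for all artifacts.
#' @return A list of class `cllscore_config`.
#' @export
run_config <- function(composition = cohort_composition(),
                       events_per_sample = 20000L, isotype_events = 5000L,
                       master_seed = 1L, gate = gate_defaults(),
                       positivity_percentile = 99.5,
                       cd200_mode = c("percent", "mfir"),
                       mfir_stat = c("mean", "median"),
                       outdir = "cllscore_run") {
  stopifnot(events_per_sample >= 1, isotype_events >= 100,
            all(composition >= 0), master_seed == floor(master_seed))
  structure(list(
    composition = composition, events_per_sample = as.integer(events_per_sample),
    isotype_events = as.integer(isotype_events),
    master_seed = as.integer(master_seed), gate = gate,
    positivity_percentile = positivity_percentile,
    cd200_mode = match.arg(cd200_mode), mfir_stat = match.arg(mfir_stat),
    outdir = outdir
  ), class = "cllscore_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; missing fields take
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cllscore_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$composition)) raw$composition <- unlist(raw$composition)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Generates the cohort on disk, analyzes every sample, scores the cohort,
#' evaluates diagnostic accuracy, and writes the report tables. A run is
#' fully reproducible from the configuration (the master seed covers every
#' source of randomness). Per-stage row counts are logged to stderr.
#'
#' Artifacts written under `config$outdir`: `manifest.csv`, per-sample event/
#' isotype/truth CSVs under `events/`, `results.csv`, `scores.csv`,
#' `accuracy.csv`, `mcnemar.csv`, and the report tables
#' `table_cd200_by_diagnosis.csv`, `table_score_crosstab.csv`,
#' `table_system_accuracy.csv`, `table_marker_accuracy.csv`, plus a
#' machine-readable `run_summary.yaml`.
#'
#' @param config A [run_config()] list.
#' @return Invisibly, a list with `manifest`, `results`, `scores`,
#'   `accuracy` (a `cllscore_accuracy` object) and `tables`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cllscore_config"))
  log_stage <- function(...) message(sprintf(...))
  manifest <- generate_cohort(config)
  log_stage("simulate: %d samples written to %s", nrow(manifest), config$outdir)
  if (nrow(manifest) == 0) abort("empty cohort: nothing to analyze")

  results <- analyze_cohort(manifest, gate = config$gate,
                            percentile = config$positivity_percentile,
                            mfir_stat = config$mfir_stat)
  readr::write_csv(results, file.path(config$outdir, "results.csv"))
  log_stage("analyze: %d samples x %d markers quantified",
            dplyr::n_distinct(results$sample_id), dplyr::n_distinct(results$marker))

  scores <- score_cohort(results, cd200_mode = config$cd200_mode)
  readr::write_csv(scores, file.path(config$outdir, "scores.csv"))
  log_stage("score: %d samples scored", nrow(scores))

  accuracy <- evaluate_accuracy(scores, manifest)
  readr::write_csv(accuracy$systems, file.path(config$outdir, "accuracy.csv"))
  readr::write_csv(accuracy$mcnemar, file.path(config$outdir, "mcnemar.csv"))
  log_stage("evaluate: %d CLL vs %d non-CLL", accuracy$n_cll, accuracy$n_non_cll)

  tables <- summarize_cohort_tables(scores, results, manifest)
  readr::write_csv(tables$cd200_by_diagnosis,
                   file.path(config$outdir, "table_cd200_by_diagnosis.csv"))
  readr::write_csv(tables$score_crosstab,
                   file.path(config$outdir, "table_score_crosstab.csv"))
  readr::write_csv(tables$system_accuracy,
                   file.path(config$outdir, "table_system_accuracy.csv"))
  readr::write_csv(tables$marker_accuracy,
                   file.path(config$outdir, "table_marker_accuracy.csv"))
  yaml::write_yaml(
    list(n_samples = nrow(manifest), n_cll = accuracy$n_cll,
         n_non_cll = accuracy$n_non_cll, master_seed = config$master_seed,
         events_per_sample = config$events_per_sample,
         cd200_mode = config$cd200_mode),
    file.path(config$outdir, "run_summary.yaml"))
  log_stage("report: tables written")
  invisible(list(manifest = manifest, results = results, scores = scores,
                 accuracy = accuracy, tables = tables))
}

#' Cohort report tables
#'
#' Builds the four report tables of a run: (a) per-diagnosis CD200 summary
#' (median and range of percent-positive and MFIR, counts at the >= 30% and
#' MFIR >= 18 cutoffs); (b) score-distribution cross-tab per system, CLL vs
#' non-CLL; (c) per-system accuracy; (d) per-marker accuracy (sensitivity,
#' specificity and AUC of each marker's point rule, with a Mann-Whitney
#' comparison of the underlying continuous value between CLL and non-CLL).
#'
#' @param scores Output of [score_cohort()].
#' @param results Output of [analyze_cohort()].
#' @param manifest Cohort manifest (needs `sample_id`, `diagnosis`, `subtype`).
#' @return A named list of tibbles: `cd200_by_diagnosis`, `score_crosstab`,
#'   `system_accuracy`, `marker_accuracy`.
#' @export
summarize_cohort_tables <- function(scores, results, manifest) {
  if (nrow(scores) == 0 || nrow(results) == 0 || nrow(manifest) == 0) {
    abort("summarize_cohort_tables needs non-empty scores, results and manifest")
  }
  meta <- manifest %>% select("sample_id", "diagnosis", "subtype")

  cd200 <- results %>%
    filter(.data$marker == "CD200") %>%
    left_join(meta, by = "sample_id") %>%
    group_by(.data$subtype) %>%
    summarise(
      n = n(),
      median_pct = median(.data$percent_positive),
      min_pct = min(.data$percent_positive), max_pct = max(.data$percent_positive),
      n_pct_ge30 = sum(.data$percent_positive >= 30),
      median_mfir = median(.data$mfir),
      min_mfir = min(.data$mfir), max_mfir = max(.data$mfir),
      n_mfir_ge18 = sum(.data$mfir >= 18), .groups = "drop")

  crosstab <- scores %>%
    left_join(meta, by = "sample_id") %>%
    mutate(group = ifelse(.data$diagnosis == "CLL", "CLL", "non-CLL")) %>%
    tidyr::pivot_longer(cols = c("classical_score", "augmented_score", "four_marker_score"),
                        names_to = "system", values_to = "score") %>%
    mutate(system = sub("_score$", "", .data$system)) %>%
    count(.data$system, .data$score, .data$group) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n", values_fill = 0L) %>%
    arrange(.data$system, dplyr::desc(.data$score))
  for (g in c("CLL", "non-CLL")) if (!g %in% names(crosstab)) crosstab[[g]] <- 0L

  acc <- evaluate_accuracy(scores, manifest)

  truth <- meta$diagnosis[match(unique(results$sample_id), meta$sample_id)] == "CLL"
  wide <- results %>%
    select("sample_id", "marker", "percent_positive", "mfir", "pattern")
  marker_rows <- purrr::map_dfr(
    c("CD200", "CD200_mfir", "CD5", "CD23", "FMC7", "CD79b", "sIgM"),
    function(m) {
      base <- sub("_mfir$", "", m)
      sub_tbl <- wide %>% filter(.data$marker == base) %>%
        arrange(match(.data$sample_id, unique(results$sample_id)))
      value <- switch(m,
        CD200_mfir = sub_tbl$mfir,
        sIgM = as.numeric(sub_tbl$pattern == "weak"),
        sub_tbl$percent_positive)
      point <- switch(m,
        CD200_mfir = value >= 18,
        FMC7 = value < 30, CD79b = value < 30,
        sIgM = value == 1,
        value >= 30)
      cm <- confusion_counts(point, truth)
      se <- proportion_ci(cm$tp, cm$tp + cm$fn)
      sp <- proportion_ci(cm$tn, cm$tn + cm$fp)
      au <- auc_ci_delong(if (m %in% c("FMC7", "CD79b")) -value else value, truth)
      mw <- mann_whitney(value[truth], value[!truth])
      tibble(marker = m,
             sensitivity = se$point, sens_lower = se$lower, sens_upper = se$upper,
             specificity = sp$point, spec_lower = sp$lower, spec_upper = sp$upper,
             auc = au$auc, auc_lower = au$lower, auc_upper = au$upper,
             p_mann_whitney = mw$p_value)
    })

  list(cd200_by_diagnosis = cd200, score_crosstab = crosstab,
       system_accuracy = acc$systems, marker_accuracy = marker_rows)
}
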