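# Listmode event simulation: a four-population scatter/CD45 mixture with a
# two-component (isotype-negative / log-normal positive) fluorescence model
# on each panel marker of the B cells.

# Scatter/CD45 location (median, linear units) and log-sd per population,
# placed so a rectangular CD45-high/SSC-low gate separates lymphocytes from
# monocytes, granulocytes and debris.
population_params <- function() {
  tibble(
    population = c("lymphocyte", "monocyte", "granulocyte", "debris"),
    weight = c(0.55, 0.12, 0.25, 0.08),
    fsc_med = c(400, 500, 450, 80),  fsc_sd = c(0.15, 0.15, 0.15, 0.50),
    ssc_med = c(150, 450, 800, 100), ssc_sd = c(0.25, 0.20, 0.20, 0.50),
    cd45_med = c(600, 500, 300, 25), cd45_sd = c(0.20, 0.20, 0.25, 0.40)
  )
}

#' Default lymphocyte gate thresholds
#'
#' Rectangular CD45-high / SSC-low gate matched to the generator's population
#' design: lymphocytes (CD45 median 600, SSC median 150) are retained while
#' granulocytes (SSC median 800) and debris (CD45 median 25) are excluded.
#'
#' @return Named list with `cd45_min` and `ssc_max`.
#' @export
gate_defaults <- function() list(cd45_min = 350, ssc_max = 300)

rln_med <- function(n, med, sdlog) rlnorm(n, meanlog = log(med), sdlog = sdlog)
# log-normal parametrised by its arithmetic mean
rln_mean <- function(n, mean, sdlog) rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)

#' Generate listmode event tables for one patient
#'
#' Draws a stained-sample event table and a matched isotype-control table
#' from one patient's marker profile. Events are a mixture of lymphocytes
#' (split into CD19+ B cells and CD19- non-B lymphocytes), monocytes,
#' granulocytes and debris. On each panel marker, B cells are a two-component
#' mixture: a negative component distributed as the isotype control and a
#' positive component at the profile's target intensity, with the positive
#' fraction equal to the target percent-positive. In the isotype tube the
#' gating channels (FSC/SSC/CD45) are stained and every panel marker,
#' including CD19, carries control fluorescence.
#'
#' @param profile One patient's profile from [sample_patient_profile()] (one
#'   row per marker).
#' @param n_events Stained-tube event count (default 20000, the acquisition
#'   scale of a routine sample).
#' @param n_isotype Isotype-tube event count (default 5000).
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @return A list with tibbles `events`, `isotype` and `truth` (per-event
#'   ground-truth population labels for both tubes; columns `tube`, `row`,
#'   `population`, `b_cell`). Attribute `low_yield` is `TRUE` when fewer than
#'   100 B cells are expected from the mixture weights; a warning is raised.
#' @export
#' @examples
#' d <- cohort_design(c("CLL-typical" = 1))
#' pr <- sample_patient_profile(d[1, ], seed = 3)
#' ev <- generate_events(pr, n_events = 2000, seed = 3)
#' head(ev$events)
generate_events <- function(profile, n_events = 20000L, n_isotype = 5000L,
                            seed = 1L) {
  stopifnot(n_events >= 1, length(unique(profile$sample_id)) == 1)
  pops <- population_params()
  iso <- iso_params()
  b_frac <- profile$b_frac[1]
  expected_b <- n_events * pops$weight[pops$population == "lymphocyte"] * b_frac
  low_yield <- expected_b < 100
  if (low_yield) {
    warn(sprintf("sample %s: expected B-cell yield %.0f is below 100; quantification will be unstable",
                 profile$sample_id[1], expected_b))
  }
  out <- with_local_seed(seed, {
    stained <- simulate_tube(n_events, pops, iso, profile, stained = TRUE, b_frac = b_frac)
    control <- simulate_tube(n_isotype, pops, iso, profile, stained = FALSE, b_frac = b_frac)
    truth <- bind_rows(
      mutate(stained$truth, tube = "events"),
      mutate(control$truth, tube = "isotype")
    ) %>% select("tube", "row", "population", "b_cell")
    list(events = stained$tab, isotype = control$tab, truth = truth)
  })
  attr(out, "low_yield") <- low_yield
  out
}

simulate_tube <- function(n, pops, iso, profile, stained, b_frac) {
  counts <- as.vector(rmultinom(1, n, pops$weight))
  pop_lab <- rep(pops$population, counts)
  n_lym <- counts[1]
  is_b <- c(rbinom(n_lym, 1, b_frac) == 1, rep(FALSE, n - n_lym))

  draw_chan <- function(med, sd) {
    unlist(purrr::map(seq_len(4), function(i) rln_med(counts[i], med[i], sd[i])))
  }
  tab <- tibble(
    FSC = draw_chan(pops$fsc_med, pops$fsc_sd),
    SSC = draw_chan(pops$ssc_med, pops$ssc_sd),
    CD45 = draw_chan(pops$cd45_med, pops$cd45_sd)
  )
  iso_draw <- function(k) rlnorm(k, iso$meanlog, iso$sdlog)

  # CD19: positive on B cells of the stained tube only
  cd19 <- iso_draw(n)
  if (stained) {
    nb <- sum(is_b)
    cd19[is_b] <- rln_mean(nb, 300, 0.25)
  }
  tab$CD19 <- cd19

  for (m in panel_markers()) {
    v <- iso_draw(n)
    if (stained) {
      row <- profile[profile$marker == m, ]
      b_idx <- which(is_b)
      pos <- rbinom(length(b_idx), 1, row$pct_target / 100) == 1
      v[b_idx[pos]] <- rln_mean(sum(pos), row$pos_mean, row$pos_sdlog)
    }
    tab[[m]] <- v
  }
  truth <- tibble(row = seq_len(n), population = pop_lab, b_cell = is_b)
  list(tab = tab[, event_columns()], truth = truth)
}

#' Simulate and analyze are composable in memory
#'
#' Convenience wrapper generating one patient end to end in memory: profile
#' draw (stream 1 of the sample's substream), event generation (stream 2).
#'
#' @param design_row One row of [cohort_design()].
#' @param master_seed Integer master seed.
#' @inheritParams generate_events
#' @return As [generate_events()], plus element `profile`.
#' @export
simulate_sample <- function(design_row, master_seed = 1L, n_events = 20000L,
                            n_isotype = 5000L) {
  off <- design_row$seed_offset[1]
  profile <- sample_patient_profile(design_row, seed = substream_seed(master_seed, off, 1L))
  ev <- generate_events(profile, n_events = n_events, n_isotype = n_isotype,
                        seed = substream_seed(master_seed, off, 2L))
  out <- c(list(profile = profile), ev)
  attr(out, "low_yield") <- attr(ev, "low_yield")
  out
}

#' Generate a synthetic cohort on disk
#'
#' Writes one stained-events CSV, one isotype CSV and one ground-truth CSV
#' per sample, plus a cohort manifest. Per-sample random streams are derived
#' deterministically from the master seed and the sample's `seed_offset`, so
#' any single sample can be regenerated in isolation. Ground-truth labels
#' live in a side file and never in the event columns, so no downstream
#' computation can consume them.
#'
#' @param config A [run_config()] list (composition, events per sample,
#'   isotype events, master seed, output directory).
#' @param master_seed Overrides `config$master_seed` when given.
#' @return The manifest tibble (also written to `manifest.csv`): `sample_id`,
#'   `diagnosis`, `subtype`, `specimen_type`, `events_path`, `isotype_path`,
#'   `truth_path`, `seed_offset`, `low_yield`.
#' @export
#' @examples
#' cfg <- run_config(composition = c(MCL = 2), events_per_sample = 1500,
#'                   outdir = tempfile("cohort"))
#' m <- generate_cohort(cfg)
#' m$sample_id
generate_cohort <- function(config, master_seed = NULL) {
  seed <- if (is.null(master_seed)) config$master_seed else master_seed
  design <- cohort_design(config$composition, seed = seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  events_dir <- file.path(config$outdir, "events")
  dir.create(events_dir, showWarnings = FALSE)
  if (nrow(design) == 0) {
    manifest <- tibble(sample_id = character(), diagnosis = character(),
                       subtype = character(), specimen_type = character(),
                       events_path = character(), isotype_path = character(),
                       truth_path = character(), seed_offset = integer(),
                       low_yield = logical())
    readr::write_csv(manifest, file.path(config$outdir, "manifest.csv"))
    return(manifest)
  }
  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    sim <- simulate_sample(design[i, ], master_seed = seed,
                           n_events = config$events_per_sample,
                           n_isotype = config$isotype_events)
    id <- design$sample_id[i]
    paths <- file.path(events_dir, paste0(id, c(".events.csv", ".isotype.csv", ".truth.csv")))
    readr::write_csv(sim$events, paths[1])
    readr::write_csv(sim$isotype, paths[2])
    readr::write_csv(sim$truth, paths[3])
    tibble(sample_id = id, diagnosis = design$diagnosis[i],
           subtype = design$subtype[i], specimen_type = design$specimen_type[i],
           events_path = paths[1], isotype_path = paths[2], truth_path = paths[3],
           seed_offset = design$seed_offset[i],
           low_yield = isTRUE(attr(sim, "low_yield")))
  })
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(config$outdir, "manifest.csv"))
  manifest
}
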