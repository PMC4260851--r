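# Configuration-driven trials and cohort experiments: wire walker, sensor,
# controller and circular statistics into reproducible runs. Everything is a
# pure function of (config, seed): sub-seeds are derived per participant and
# per condition by a counter scheme.

#' Experiment configuration
#'
#' @param strategy,start_phase_deg,... Passed to [strategy_config()].
#' @param library A `song_library` (or path to one, loaded via
#'   [load_library()]).
#' @param duration_s Trial duration in seconds (default 600).
#' @param cohort A [make_cohort()] tibble (used by [run_cohort()]).
#' @param sensor A [sensor_params()] or NULL to disable sensor quantisation.
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(strategy = 1, start_phase_deg = 0,
                              library = synthetic_library(),
                              duration_s = 600, cohort = NULL,
                              sensor = sensor_params(), seed = 1, ...) {
  if (is.character(library)) library <- load_library(library)
  stopifnot(duration_s > 0)
  structure(
    list(strategy_cfg = strategy_config(strategy = strategy,
                                        start_phase_deg = start_phase_deg, ...),
         library = library, duration_s = duration_s, cohort = cohort,
         sensor = sensor, seed = seed),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the [strategy_config()] and [experiment_config()] argument
#' names (`strategy`, `start_phase_deg`, `band_deg`, `nudge`, `debounce_s`,
#' `duration_s`, `seed`, `library` as a path, `n_participants`,
#' `nonentrainer_fraction`, ...).
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values (e.g. from CLI flags).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  n_part <- raw$n_participants %||% 10
  seed <- raw$seed %||% 1
  cohort_ranges <- raw$param_ranges %||% list()
  cohort <- make_cohort(n_part, param_ranges = cohort_ranges, seed = seed,
                        nonentrainer_fraction = raw$nonentrainer_fraction %||% 0.2)
  args <- raw[intersect(names(raw),
                        c("strategy", "start_phase_deg", "band_deg", "nudge",
                          "debounce_s", "avg_window_steps", "harmonic_margin",
                          "quantise", "duration_s", "seed"))]
  args$library <- if (!is.null(raw$library)) load_library(raw$library) else synthetic_library()
  args$cohort <- cohort
  do.call(experiment_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run one closed-loop trial
#'
#' Simulates a single walker against the configured controller for
#' `duration_s` seconds, computes per-step relative phases from the emitted
#' logs, and summarises them. Output is bit-identical for identical
#' (config, walker, seed).
#'
#' @param cfg An [experiment_config()].
#' @param walker A [walker_params()] (e.g. [cohort_walker()] on a cohort
#'   row).
#' @param seed Trial seed (default: the config's master seed).
#' @param scenario Optional [scenario_events()] tibble of disturbances.
#' @param output_dir Optional directory; when given, `footfalls.csv`,
#'   `beats.csv`, `trace.csv` and `phases.csv` are written there.
#' @return A list of class `trial_result`: `footfalls`, `beats`, `phases`,
#'   `trace` tibbles plus `summary` (a [phase_summary()] row with the
#'   participant id prepended).
#' @export
run_trial <- function(cfg, walker, seed = cfg$seed, scenario = NULL,
                      output_dir = NULL) {
  st <- new_strategy_state(cfg$library, cfg$strategy_cfg)
  cb <- strategy_player_callback(st, sensor = cfg$sensor)
  footfalls <- withr::with_seed(seed, {
    simulate_walk(walker, cb, cfg$duration_s, scenario = scenario)
  })
  detected <- if (is.null(cfg$sensor)) footfalls else quantise_events(footfalls, cfg$sensor)
  res <- controller_results(st)
  phases <- phase_series(detected, res$beats)
  if (!("participant_id" %in% names(phases))) {
    phases <- tibble::add_column(phases,
      participant_id = rep(walker$participant_id, nrow(phases)), .before = 1)
  }
  summ <- if (nrow(phases) > 0) {
    phase_summary(phases$phi_display)
  } else {
    tibble::tibble(n = 0L, mean_angle_deg = NA_real_, ci95_low_deg = NA_real_,
                   ci95_high_deg = NA_real_, R = NA_real_, V = NA_real_,
                   s = NA_real_, b = NA_real_, k = NA_real_)
  }
  summ <- tibble::add_column(summ, participant_id = walker$participant_id,
                             .before = 1)
  out <- structure(
    list(footfalls = footfalls, beats = res$beats, phases = phases,
         trace = res$trace, summary = summ),
    class = "trial_result"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_footfalls(footfalls, file.path(output_dir, "footfalls.csv"))
    write_beats(res$beats, file.path(output_dir, "beats.csv"))
    readr::write_csv(res$trace, file.path(output_dir, "trace.csv"))
    write_phases(phases, file.path(output_dir, "phases.csv"))
  }
  out
}

#' Run a cohort experiment
#'
#' Runs every cohort participant through one or more conditions, pools the
#' phases per condition, and assembles the full analysis: pooled
#' eight-parameter summaries, per-participant resultant lengths and Rayleigh
#' classification, the synchronised fraction, uniformity tests per condition,
#' and — when exactly two conditions are configured (e.g. song starts at 0
#' versus 180 degrees) — the two-sample Watson U2 comparison.
#'
#' @param cfg An [experiment_config()] with a non-NULL `cohort`.
#' @param conditions Optional named list of condition-specific overrides,
#'   each a list with any of `strategy`, `start_phase_deg`; default one
#'   condition named after the configured strategy.
#' @param alpha Per-participant Rayleigh level (default 0.05).
#' @return A list of class `cohort_report`: `pooled` (one `phase_summary`
#'   row per condition, condition column first), `per_participant`,
#'   `sync_fraction` (per condition), `uniformity` (Rayleigh and
#'   Hodges-Ajne per condition, tidied), `comparison` (tidied Watson U2 or
#'   NULL), `phases` (all samples with a `condition` column).
#' @export
run_cohort <- function(cfg, conditions = NULL, alpha = 0.05) {
  if (is.null(cfg$cohort)) {
    abort("config has no cohort", class = "gaitsync_config")
  }
  if (is.null(conditions)) {
    nm <- paste0("strategy", cfg$strategy_cfg$strategy,
                 if (cfg$strategy_cfg$strategy == 3L)
                   paste0("_", cfg$strategy_cfg$start_phase_deg) else "")
    conditions <- stats::setNames(list(list()), nm)
  }
  all_phases <- purrr::imap(conditions, function(ov, cond_name) {
    ccfg <- cfg
    if (!is.null(ov$strategy) || !is.null(ov$start_phase_deg)) {
      sc <- cfg$strategy_cfg
      ccfg$strategy_cfg <- strategy_config(
        strategy = ov$strategy %||% sc$strategy,
        start_phase_deg = ov$start_phase_deg %||% sc$start_phase_deg,
        band_deg = sc$band_deg, nudge = sc$nudge, clamp = sc$clamp,
        debounce_s = sc$debounce_s, avg_window_steps = sc$avg_window_steps,
        harmonic_margin = sc$harmonic_margin, quantise = sc$quantise,
        exclude_played = sc$exclude_played)
    }
    cond_i <- match(cond_name, names(conditions))
    rows <- purrr::map(seq_len(nrow(cfg$cohort)), function(i) {
      trial <- run_trial(ccfg, cohort_walker(cfg$cohort[i, ]),
                         seed = derive_seed(cfg$seed, i * 131 + cond_i))
      trial$phases
    })
    ph <- dplyr::bind_rows(rows)
    if (nrow(ph) > 0) ph$condition <- cond_name
    ph
  })
  phases <- dplyr::bind_rows(all_phases)
  by_cond <- split(phases, phases$condition)
  pooled <- dplyr::bind_rows(purrr::imap(by_cond, function(ph, nm) {
    tibble::add_column(phase_summary(ph$phi_display), condition = nm, .before = 1)
  }))
  per_part <- dplyr::bind_rows(purrr::imap(by_cond, function(ph, nm) {
    res <- participant_sync_fraction(ph, alpha = alpha)
    tibble::add_column(res$per_participant, condition = nm, .before = 1)
  }))
  sync <- dplyr::summarise(dplyr::group_by(per_part, .data$condition),
                           sync_fraction = mean(.data$synchronised),
                           .groups = "drop")
  uniformity <- dplyr::bind_rows(purrr::imap(by_cond, function(ph, nm) {
    dplyr::bind_rows(tidy(rayleigh_test(ph$phi_display)),
                     tidy(hodges_ajne_test(ph$phi_display))) |>
      tibble::add_column(condition = nm, .before = 1)
  }))
  comparison <- NULL
  if (length(by_cond) == 2) {
    comparison <- tidy(watson_u2_two_sample(by_cond[[1]]$phi_display,
                                            by_cond[[2]]$phi_display))
    comparison$conditions <- paste(names(by_cond), collapse = " vs ")
  }
  structure(
    list(pooled = pooled, per_participant = per_part, sync_fraction = sync,
         uniformity = uniformity, comparison = comparison, phases = phases),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n\nPooled circular summaries:\n")
  print(x$pooled)
  cat("\nSynchronised fraction per condition:\n")
  print(x$sync_fraction)
  if (!is.null(x$comparison)) {
    cat("\nCondition comparison (Watson U2):\n")
    print(x$comparison)
  }
  invisible(x)
}

#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$pooled

#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  dplyr::left_join(
    dplyr::summarise(dplyr::group_by(x$per_participant, .data$condition),
                     n_participants = dplyr::n(),
                     mean_R = mean(.data$R), .groups = "drop"),
    x$sync_fraction, by = "condition")
}

#' Write a cohort report to files
#'
#' The summary table is laid out with one row per circular parameter (mean
#' angle, confidence limits, R, V, s, b, k) and one column per condition,
#' plus a per-participant resultant-length listing.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if missing).
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @return Paths of the written files, invisibly.
#' @export
report_files <- function(report, dir, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- summary_table(report$pooled)
  paths <- character(0)
  if (format == "csv") {
    p1 <- file.path(dir, "summary.csv")
    readr::write_csv(wide, p1)
    p2 <- file.path(dir, "per_participant.csv")
    readr::write_csv(report$per_participant, p2)
    paths <- c(p1, p2)
  } else if (format == "json") {
    p1 <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(schema_version = "1.0",
           pooled = report$pooled,
           per_participant = report$per_participant,
           sync_fraction = report$sync_fraction,
           uniformity = report$uniformity,
           comparison = report$comparison),
      p1, dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
    paths <- p1
  } else {
    p1 <- file.path(dir, "report.md")
    lines <- c(md_table(wide), "", "Per-participant resultant lengths:", "",
               md_table(dplyr::select(report$per_participant,
                                      "condition", "participant_id", "n", "R",
                                      "p_value", "synchronised")))
    writeLines(lines, p1)
    paths <- p1
  }
  invisible(paths)
}

# parameters as rows, conditions as columns
summary_table <- function(pooled) {
  long <- tidyr::pivot_longer(pooled,
                              cols = c("mean_angle_deg", "ci95_high_deg",
                                       "ci95_low_deg", "R", "V", "s", "b", "k"),
                              names_to = "parameter", values_to = "value")
  tidyr::pivot_wider(long[c("parameter", "condition", "value")],
                     names_from = "condition", values_from = "value")
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(purrr::map_chr(cells, function(col) col[[i]]), collapse = " | "), " |")
  })
  c(header, sep, rows)
}
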