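# End-to-end orchestration: calibrate -> profile -> aggregate -> ANOVA,
# driven by a single YAML config, with per-entry error isolation and
# publication-shaped CSV reports.

default_pipeline_params <- function() {
  list(
    processing = list(window_duration = 0.1, step_duration = 0.05,
                      rest_threshold = 0.5, min_gap_duration = 0.25,
                      percentiles = c(0.10, 0.50, 0.90),
                      subtract_baseline = FALSE),
    calibration = list(window_duration = 3, trial_statistic = "max",
                       prefilter = NULL),
    statistics = list(alpha = 0.05, adjustment = "tukey-mvt"),
    log_level = "info"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys: `manifest` (path, required), `output_dir`, and optional
#' `processing`, `calibration`, `statistics` blocks overriding the
#' defaults of [default_pipeline_params()]. Relative paths resolve
#' against the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    semg_stop(sprintf("config not found: %s", path), "semg_io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$manifest))
    semg_stop("config must name a manifest", "semg_invalid_argument")
  cfg <- utils::modifyList(default_pipeline_params(), y)
  if (!is.null(cfg$processing$percentiles) &&
      is.unsorted(cfg$processing$percentiles))
    semg_stop("percentile list must be sorted", "semg_invalid_argument")
  root <- dirname(normalizePath(path))
  if (!grepl("^(/|[A-Za-z]:)", cfg$manifest))
    cfg$manifest <- file.path(root, cfg$manifest)
  if (!is.null(cfg$output_dir) && !grepl("^(/|[A-Za-z]:)", cfg$output_dir))
    cfg$output_dir <- file.path(root, cfg$output_dir)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

read_entry_recording <- function(manifest, path, ...) {
  read_recording(manifest_path(manifest, path),
                 sampling_rate = manifest$sampling_rate, ...)
}

#' Run the full analysis pipeline
#'
#' For every manifest entry: read the baseline and fMVC trials, derive the
#' calibration ([calibrate()]), read the work recording and build its
#' activity profile ([build_profile()]) and exposure assessment. Entries
#' that fail at any stage are skipped with a logged reason; the run fails
#' only when no complete subject remains. Per-subject metrics are then
#' aggregated by group x muscle and each metric is analyzed with the
#' random-block ANOVA and simple main effects of group within muscle.
#'
#' Outputs written to `out_dir`: `metrics_long.csv` (full precision),
#' `summary_<metric>.csv` and `simple_effects_<metric>.csv` (two
#' decimals, matching conventional report tables), `exposure.csv`,
#' `anova_<metric>.csv`, `skipped.csv` (if any), `run_log.txt` and a
#' `config_echo.yaml` sufficient to reproduce the run.
#'
#' @param config A `pipeline_config` (or path to one, or a plain list).
#' @param out_dir Output directory; defaults to `config$output_dir`.
#' @param metric Restrict the statistical stage to one metric (default:
#'   all five).
#' @return An object of class `run_report` (invisibly written to disk):
#'   list with `metrics` (long data frame), `summaries`,
#'   `simple_effects`, `anova`, `exposure`, `skipped`, `warnings`,
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, metric = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config))
    semg_stop("config must be a pipeline_config or a path",
              "semg_invalid_argument")
  cfg <- utils::modifyList(default_pipeline_params(), unclass(config))
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  if (is.null(out_dir))
    semg_stop("an output directory is required", "semg_invalid_argument")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logit <- function(level, msg) {
    line <- sprintf("[%s] %s", level, msg)
    log_lines <<- c(log_lines, line)
    if (cfg$log_level != "quiet") message(line)
  }

  manifest <- if (inherits(cfg$manifest, "cohort_manifest")) cfg$manifest
              else read_manifest(cfg$manifest)
  e <- manifest$entries
  pr <- cfg$processing; cb <- cfg$calibration
  metrics <- list(); exposures <- list(); skipped <- list()
  warn_log <- character()

  for (i in seq_len(nrow(e))) {
    tag <- sprintf("%s/%s", e$subject_id[i], e$muscle[i])
    res <- tryCatch({
      withCallingHandlers({
        baseline <- read_entry_recording(manifest, e$baseline[i],
                                         subject_id = e$subject_id[i],
                                         group = e$group[i],
                                         muscle = e$muscle[i],
                                         session_kind = "baseline")
        trials <- lapply(e$fmvc_trials[[i]], function(p)
          read_entry_recording(manifest, p, subject_id = e$subject_id[i],
                               group = e$group[i], muscle = e$muscle[i],
                               session_kind = "fmvc_trial"))
        work <- read_entry_recording(manifest, e$work[i],
                                     subject_id = e$subject_id[i],
                                     group = e$group[i],
                                     muscle = e$muscle[i],
                                     session_kind = "work")
        if (!is.null(cb$prefilter)) {
          flt <- function(r) bandpass_filter(r, cb$prefilter$low,
                                             cb$prefilter$high)
          baseline <- flt(baseline); work <- flt(work)
          trials <- lapply(trials, flt)
        }
        cal <- calibrate(calibration_set(baseline, trials,
                                         subject_id = e$subject_id[i],
                                         muscle = e$muscle[i]),
                         window_duration = cb$window_duration,
                         trial_statistic = cb$trial_statistic)
        prof <- build_profile(work, cal,
                              window_duration = pr$window_duration,
                              step_duration = pr$step_duration,
                              rest_threshold = pr$rest_threshold,
                              min_gap_duration = pr$min_gap_duration,
                              percentiles = pr$percentiles,
                              subtract_baseline = pr$subtract_baseline)
        list(rows = profile_to_rows(prof, e$subject_id[i], e$group[i],
                                    e$muscle[i]),
             exposure = cbind(subject = e$subject_id[i],
                              group = e$group[i], muscle = e$muscle[i],
                              as.data.frame(classify_exposure(prof))))
      }, warning = function(w) {
        warn_log <<- c(warn_log, sprintf("%s: %s", tag, conditionMessage(w)))
        logit("warn", sprintf("%s: %s", tag, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }, error = function(err) err)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        subject = e$subject_id[i], muscle = e$muscle[i],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      logit("warn", sprintf("skipping %s: %s", tag, conditionMessage(res)))
    } else {
      metrics[[length(metrics) + 1L]] <- res$rows
      exposures[[length(exposures) + 1L]] <- res$exposure
      logit("info", sprintf("processed %s", tag))
    }
  }

  if (!length(metrics))
    semg_stop("no manifest entry could be processed", "semg_pipeline_error")
  long <- do.call(rbind, metrics)
  exposure <- do.call(rbind, exposures)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL

  write_long_table(long, file.path(out_dir, "metrics_long.csv"))
  utils::write.csv(exposure, file.path(out_dir, "exposure.csv"),
                   row.names = FALSE)
  if (!is.null(skipped))
    utils::write.csv(skipped, file.path(out_dir, "skipped.csv"),
                     row.names = FALSE)

  which_metrics <- if (is.null(metric)) unique(long$metric) else metric
  summaries <- list(); effects <- list(); anovas <- list()
  for (m in which_metrics) {
    sm <- aggregate_profiles(long[long$metric == m, ])
    summaries[[m]] <- sm
    rounded <- sm
    rounded$mean <- round(rounded$mean, 2); rounded$sd <- round(rounded$sd, 2)
    utils::write.csv(rounded,
                     file.path(out_dir, sprintf("summary_%s.csv", m)),
                     row.names = FALSE)
    fit <- tryCatch(fit_random_block_anova(long, m,
                                           alpha = cfg$statistics$alpha),
                    error = function(err) err)
    if (inherits(fit, "error")) {
      logit("warn", sprintf("ANOVA for %s failed: %s", m,
                            conditionMessage(fit)))
      next
    }
    anovas[[m]] <- fit
    utils::write.csv(fit$terms,
                     file.path(out_dir, sprintf("anova_%s.csv", m)),
                     row.names = FALSE)
    sme <- simple_main_effects(fit)
    effects[[m]] <- sme
    out <- as.data.frame(sme)
    for (col in c("estimate_group_a", "estimate_group_b", "delta"))
      out[[col]] <- round(out[[col]], 2)
    utils::write.csv(out,
                     file.path(out_dir, sprintf("simple_effects_%s.csv", m)),
                     row.names = FALSE)
  }

  echo <- unclass(cfg)
  echo$manifest <- if (inherits(cfg$manifest, "cohort_manifest"))
    "<in-memory manifest>" else cfg$manifest
  echo$package_version <- as.character(utils::packageVersion("semgprofile"))
  yaml::write_yaml(echo, file.path(out_dir, "config_echo.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  structure(
    list(metrics = long, summaries = summaries, simple_effects = effects,
         anova = anovas, exposure = exposure, skipped = skipped,
         warnings = warn_log, config = cfg, out_dir = out_dir),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d recordings processed, %d skipped\n",
              length(unique(paste(x$metrics$subject, x$metrics$muscle))),
              if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  cat(sprintf("  metrics: %s\n", paste(names(x$summaries), collapse = ", ")))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}

#' Simulate a cohort to disk (the `simulate` command)
#'
#' Runs [simulate_cohort()] and additionally writes the per-subject
#' analytic ground truth (`ground_truth.csv`) and the group x muscle
#' truth matrix (`truth_matrix.csv`) so downstream recovery can be
#' scored. The generated directory is directly consumable by
#' [run_pipeline()].
#'
#' @param config A [simulation_config()], or path to a YAML file with
#'   keys matching its arguments (plus an optional `cohort` block).
#' @param out_dir Output directory.
#' @return The [simulate_cohort()] result, invisibly.
#' @export
simulate_command <- function(config, out_dir) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    y$noise_band <- if (is.null(y$noise_band)) c(20, 450)
                    else as.numeric(unlist(y$noise_band))
    config <- simulation_config(
      seed = y$seed,
      sampling_rate = if (is.null(y$sampling_rate)) 1000 else y$sampling_rate,
      noise_band = y$noise_band,
      mvc_reference_amplitude = if (is.null(y$mvc_reference_amplitude)) 1
                                else y$mvc_reference_amplitude,
      cohort = y$cohort)
  }
  sim <- simulate_cohort(config, out_dir)
  utils::write.csv(sim$subject_truth,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  tm <- as.data.frame(sim$truth_matrix)
  tm <- cbind(group = rownames(tm), tm)
  utils::write.csv(tm, file.path(out_dir, "truth_matrix.csv"),
                   row.names = FALSE)
  invisible(sim)
}
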