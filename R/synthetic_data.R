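# Synthetic sEMG generator: band-limited Gaussian carrier, amplitude
# modulated by a task schedule with known %MVC targets, so every pipeline
# stage can be scored against analytic ground truth. Segment RMS is exact
# by construction (each segment is rescaled to its target RMS), which
# keeps recovery tolerances tight.

#' Task schedule
#'
#' Ordered activity segments that tile a recording exactly: each segment
#' has a label, a duration in seconds and a target amplitude in %MVC
#' (RMS of the carrier relative to the 100 %MVC reference amplitude).
#'
#' @param label Character vector of segment labels.
#' @param duration Segment durations in seconds, all positive.
#' @param amplitude Target amplitudes in %MVC, all non-negative.
#' @return An object of class `task_schedule` (a data frame with an
#'   attribute `total_duration`).
#' @export
task_schedule <- function(label, duration, amplitude) {
  if (!length(duration) || length(duration) != length(amplitude) ||
      length(label) != length(duration))
    semg_stop("label, duration and amplitude must have equal, positive length",
              "semg_invalid_argument")
  if (any(duration <= 0) || any(amplitude < 0) ||
      !all(is.finite(c(duration, amplitude))))
    semg_stop("durations must be positive and amplitudes non-negative",
              "semg_invalid_argument")
  out <- data.frame(label = as.character(label), duration = duration,
                    amplitude = amplitude, stringsAsFactors = FALSE)
  attr(out, "total_duration") <- sum(duration)
  class(out) <- c("task_schedule", "data.frame")
  out
}

#' Alternating rest/work schedule
#'
#' Builds a cyclic schedule with a prescribed rest fraction delivered in
#' fixed-length rest bouts, the structure used to exercise the percent
#' muscular rest metric. Each cycle is one rest bout of `rest_bout`
#' seconds at `rest_level` %MVC followed by one work bout at `work_level`
#' %MVC sized so rest occupies `rest_fraction` of the cycle; cycles repeat
#' until `total_duration` is tiled (the last cycle is truncated).
#'
#' @param total_duration Recording length, seconds.
#' @param work_level Work amplitude, %MVC.
#' @param rest_fraction Fraction of time at rest, in (0, 1).
#' @param rest_bout Rest bout length, seconds (default 1).
#' @param rest_level Rest amplitude, %MVC; keep at or below 0.5 so the
#'   bout counts as rest under the gap rule (default 0.2).
#' @return A [task_schedule()].
#' @export
rest_work_schedule <- function(total_duration, work_level,
                               rest_fraction = 0.3, rest_bout = 1,
                               rest_level = 0.2) {
  if (rest_fraction <= 0 || rest_fraction >= 1)
    semg_stop("rest_fraction must lie in (0, 1)", "semg_invalid_argument")
  work_bout <- rest_bout * (1 - rest_fraction) / rest_fraction
  cycle <- rest_bout + work_bout
  n_full <- floor(total_duration / cycle)
  lab <- rep(c("rest", "work"), n_full)
  dur <- rep(c(rest_bout, work_bout), n_full)
  amp <- rep(c(rest_level, work_level), n_full)
  rem <- total_duration - n_full * cycle
  if (rem > 1e-9) {
    if (rem <= rest_bout) {
      lab <- c(lab, "rest"); dur <- c(dur, rem); amp <- c(amp, rest_level)
    } else {
      lab <- c(lab, "rest", "work")
      dur <- c(dur, rest_bout, rem - rest_bout)
      amp <- c(amp, rest_level, work_level)
    }
  }
  task_schedule(lab, dur, amp)
}

#' Canonical milking-task cycle schedule
#'
#' A repeating 10-s parlor work cycle with one 3-s rest bout and the five
#' milking tasks (pre-dipping, stripping, wiping, attaching,
#' post-dipping) at graded intensities, giving a 30% scheduled rest
#' fraction. Task levels are chosen so the schedule's theoretical median
#' amplitude falls inside a task plateau rather than on a boundary of the
#' duration-weighted amplitude distribution, which keeps the empirical
#' APDF median an unbiased estimate of the analytic one (see the package
#' vignette).
#'
#' @param n_cycles Number of cycles (default 60, a 10-minute recording).
#' @param rest_bout Rest bout length per cycle, seconds (default 3).
#' @param rest_level Rest amplitude in %MVC (default 0.2).
#' @param intensity Multiplier applied to all task (non-rest) amplitudes.
#' @return A [task_schedule()].
#' @export
milking_schedule <- function(n_cycles = 60, rest_bout = 3, rest_level = 0.2,
                             intensity = 1) {
  cyc_lab <- c("rest", "pre_dip", "strip", "wipe", "attach", "post_dip")
  cyc_dur <- c(rest_bout, 0.4, 2.5, 1.9, 1.8, 0.4)
  cyc_amp <- c(rest_level, 8 * intensity, 15 * intensity, 25 * intensity,
               35 * intensity, 8 * intensity)
  task_schedule(rep(cyc_lab, n_cycles), rep(cyc_dur, n_cycles),
                rep(cyc_amp, n_cycles))
}

#' Analytic ground truth of a schedule
#'
#' Computes, from segment durations and amplitudes alone (never from
#' realized noise): the duration-weighted mean envelope in %fMVC, the
#' theoretical APDF percentiles of the duration-weighted amplitude
#' distribution (midpoint convention when a probability falls exactly on
#' the boundary between two amplitude levels), and the scheduled rest
#' fraction -- the share of time in merged runs of consecutive segments at
#' or below `rest_threshold` %MVC lasting at least `min_gap_duration`,
#' i.e. the same inclusion rule the percent muscular rest metric applies.
#'
#' @param schedule A [task_schedule()].
#' @param percentiles APDF probabilities (default 0.1, 0.5, 0.9).
#' @param rest_threshold,min_gap_duration Rest gap rule (defaults 0.5
#'   %MVC, 0.25 s).
#' @return List with `mean_envelope`, `apdf` (named vector),
#'   `rest_fraction_percent`, `total_duration` and the schedule.
#' @export
schedule_ground_truth <- function(schedule, percentiles = c(0.1, 0.5, 0.9),
                                  rest_threshold = 0.5,
                                  min_gap_duration = 0.25) {
  stopifnot(inherits(schedule, "task_schedule"))
  tot <- sum(schedule$duration)
  w <- schedule$duration / tot

  mean_env <- sum(w * schedule$amplitude)

  # duration-weighted discrete amplitude distribution
  amps <- sort(unique(schedule$amplitude))
  mass <- vapply(amps, function(a) sum(w[schedule$amplitude == a]),
                 numeric(1))
  cw <- cumsum(mass)
  qfun <- function(p) {
    i <- which(cw >= p - 1e-12)[1L]
    if (abs(cw[i] - p) < 1e-12 && i < length(amps))
      (amps[i] + amps[i + 1L]) / 2
    else amps[i]
  }
  apdf <- vapply(percentiles, qfun, numeric(1))
  names(apdf) <- paste0("p", formatC(100 * percentiles, format = "g"))

  # merge consecutive sub-threshold segments into bouts, then apply the
  # minimum-gap rule
  is_rest <- schedule$amplitude <= rest_threshold
  r <- rle(is_rest)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  bout <- vapply(seq_along(r$values), function(j)
    sum(schedule$duration[idx_start[j]:idx_end[j]]), numeric(1))
  rest_time <- sum(bout[r$values & bout >= min_gap_duration - 1e-9])

  list(mean_envelope = mean_env, apdf = apdf,
       rest_fraction_percent = 100 * rest_time / tot,
       total_duration = tot, schedule = schedule)
}

#' Simulation configuration
#'
#' @param seed Master seed (integer); all child streams derive from it.
#' @param sampling_rate Hz (default 1000).
#' @param noise_band Carrier band edges in Hz (default 20-450, the
#'   standard sEMG bandwidth at a 1000-Hz sampling rate).
#' @param mvc_reference_amplitude Carrier RMS, in instrument units, that
#'   corresponds to 100 %MVC (default 1).
#' @param schedule Optional default [task_schedule()] for
#'   [simulate_recording()].
#' @param cohort Optional cohort block for [simulate_cohort()]: a list
#'   with `work_duration`, `rest_bout` and `groups`, where `groups` is a
#'   named list of `list(n_subjects, muscle_levels, between_subject_sd,
#'   rest_fraction)` entries (see the package vignette).
#' @param filter_order Butterworth order of the carrier filter.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed, sampling_rate = 1000,
                              noise_band = c(20, 450),
                              mvc_reference_amplitude = 1,
                              schedule = NULL, cohort = NULL,
                              filter_order = 4) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    semg_stop("seed must be a single integer", "semg_invalid_argument")
  if (length(noise_band) != 2L || !(noise_band[1] > 0) ||
      !(noise_band[1] < noise_band[2]) ||
      !(noise_band[2] < sampling_rate / 2))
    semg_stop(sprintf(
      "noise_band must satisfy 0 < low < high < %g Hz (Nyquist)",
      sampling_rate / 2), "semg_invalid_argument")
  if (mvc_reference_amplitude <= 0)
    semg_stop("mvc_reference_amplitude must be positive",
              "semg_invalid_argument")
  structure(
    list(seed = as.integer(seed), sampling_rate = sampling_rate,
         noise_band = noise_band,
         mvc_reference_amplitude = mvc_reference_amplitude,
         schedule = schedule, cohort = cohort, filter_order = filter_order),
    class = "simulation_config"
  )
}

# Band-limited unit-variance-ish Gaussian carrier of n samples. The exact
# realized gain is irrelevant: each schedule segment is rescaled to its
# target RMS afterwards.
simulate_carrier <- function(n, config) {
  x <- rnorm(n)
  nyq <- config$sampling_rate / 2
  bf <- signal::butter(config$filter_order, config$noise_band / nyq,
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Segment boundaries in samples from rounded cumulative durations,
# avoiding drift over many segments.
segment_bounds <- function(schedule, fs) {
  ends <- round(cumsum(schedule$duration) * fs)
  starts <- c(0, ends[-length(ends)]) + 1L
  if (any(ends - starts + 1L < 1L))
    semg_stop("a schedule segment is shorter than one sample",
              "semg_invalid_argument")
  cbind(start = starts, end = ends)
}

#' Simulate one sEMG recording from a task schedule
#'
#' Generates a zero-mean Gaussian carrier band-limited to
#' `config$noise_band` and rescales each schedule segment so its realized
#' RMS equals `(amplitude / 100) * mvc_reference_amplitude` exactly
#' (segments at 0 %MVC are exactly zero). Deterministic for a fixed
#' seed. The returned ground truth is computed analytically from the
#' schedule, never from the realized signal.
#'
#' @param config A [simulation_config()].
#' @param schedule A [task_schedule()]; defaults to `config$schedule`.
#' @param seed Seed for this recording; defaults to `config$seed`.
#' @param subject_id,group,muscle,session_kind Labels for the recording.
#' @return List with elements `recording` ([emg_recording()]) and
#'   `ground_truth` ([schedule_ground_truth()]).
#' @export
simulate_recording <- function(config, schedule = config$schedule,
                               seed = config$seed,
                               subject_id = "sim", group = NA_character_,
                               muscle = NA_character_,
                               session_kind = "work") {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(schedule) || !inherits(schedule, "task_schedule"))
    semg_stop("a task_schedule is required", "semg_invalid_argument")
  fs <- config$sampling_rate
  bounds <- segment_bounds(schedule, fs)
  n <- bounds[nrow(bounds), "end"]
  x <- with_local_seed(seed, simulate_carrier(n, config))
  for (i in seq_len(nrow(bounds))) {
    idx <- bounds[i, "start"]:bounds[i, "end"]
    target <- schedule$amplitude[i] / 100 * config$mvc_reference_amplitude
    if (target == 0) {
      x[idx] <- 0
    } else {
      realized <- sqrt(mean(x[idx]^2))
      x[idx] <- x[idx] * (target / realized)
    }
  }
  rec <- emg_recording(x, sampling_rate = fs, subject_id = subject_id,
                       group = group, muscle = muscle,
                       session_kind = session_kind)
  list(recording = rec, ground_truth = schedule_ground_truth(schedule))
}

#' Simulate a calibration set
#'
#' Mirrors the field calibration protocol: one 30-s baseline recording at
#' a low resting level and three 5-s maximal-effort trials at 100 %MVC,
#' with child seeds derived deterministically from the master seed.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed for this calibration (default `config$seed`).
#' @param baseline_level Baseline amplitude in %MVC (default 0.2).
#' @param baseline_duration Baseline length, seconds (default 30).
#' @param n_trials Number of fMVC trials (default 3).
#' @param trial_duration Trial length, seconds (default 5).
#' @param trial_levels Trial amplitudes in %MVC (default all 100).
#' @param subject_id,muscle Labels.
#' @return A [calibration_set()].
#' @export
simulate_calibration <- function(config, seed = config$seed,
                                 baseline_level = 0.2,
                                 baseline_duration = 30, n_trials = 3,
                                 trial_duration = 5,
                                 trial_levels = rep(100, n_trials),
                                 subject_id = "sim",
                                 muscle = NA_character_) {
  stopifnot(inherits(config, "simulation_config"))
  base <- simulate_recording(
    config, task_schedule("baseline", baseline_duration, baseline_level),
    seed = child_seed(seed, 1L), subject_id = subject_id, muscle = muscle,
    session_kind = "baseline")$recording
  trials <- lapply(seq_len(n_trials), function(i)
    simulate_recording(
      config, task_schedule("fmvc", trial_duration, trial_levels[i]),
      seed = child_seed(seed, 1L + i), subject_id = subject_id,
      muscle = muscle, session_kind = "fmvc_trial")$recording)
  calibration_set(base, trials, subject_id = subject_id, muscle = muscle)
}

# Default cohort block: 2 groups x 6 subjects x 5 muscles. Mean %MVC
# levels loosely follow the magnitude ordering seen in milking-parlor
# work (biceps and wrist muscles loaded hardest in the large-herd group),
# with moderate between-subject spread; recordings are 60-s demo length.
default_cohort_block <- function() {
  list(
    work_duration = 60,
    rest_bout = 1,
    groups = list(
      large_herd_US = list(
        n_subjects = 6,
        muscle_levels = c(upper_trapezius = 14, anterior_deltoid = 10,
                          biceps_brachii = 19, wrist_flexors = 13,
                          wrist_extensors = 14),
        between_subject_sd = 3,
        rest_fraction = 0.12
      ),
      small_herd_IT = list(
        n_subjects = 6,
        muscle_levels = c(upper_trapezius = 8, anterior_deltoid = 8,
                          biceps_brachii = 7, wrist_flexors = 6,
                          wrist_extensors = 15),
        between_subject_sd = 3,
        rest_fraction = 0.05
      )
    )
  )
}

#' Simulate a whole cohort and write it in pipeline input format
#'
#' Draws, for every subject x muscle, a subject-level work intensity
#' `truth + Normal(0, between_subject_sd)` (floored at zero), simulates a
#' rest/work recording at that intensity plus a calibration set, writes
#' all signal files via [write_recording()] and a YAML manifest via
#' [write_manifest()], and returns the analytic ground truth so recovery
#' of group x muscle means and of the ANOVA effects can be scored.
#'
#' @param config A [simulation_config()] whose `cohort` block is set
#'   (defaults to a 2 x 6 x 5 demo cohort with 60-s recordings).
#' @param out_dir Directory to create the files in.
#' @return List with `manifest` (a [cohort_manifest()]), `manifest_path`,
#'   `subject_truth` (data frame: group, subject, muscle, true level and
#'   per-recording scheduled ground truth), and `truth_matrix` (the group
#'   x muscle mean %MVC matrix the cohort was drawn from).
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- if (is.null(config$cohort)) default_cohort_block()
            else config$cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  entries <- list(); truth_rows <- list()
  k <- 0L
  for (gname in names(cohort$groups)) {
    g <- cohort$groups[[gname]]
    if (g$n_subjects < 2L)
      semg_stop("each group needs at least two subjects",
                "semg_invalid_argument")
    muscles <- names(g$muscle_levels)
    for (si in seq_len(g$n_subjects)) {
      sid <- sprintf("%s_S%02d", gname, si)
      for (mi in seq_along(muscles)) {
        k <- k + 1L
        mname <- muscles[mi]
        seed_k <- child_seed(config$seed, k)
        level <- with_local_seed(child_seed(seed_k, 97L), {
          max(0, g$muscle_levels[[mi]] + rnorm(1, 0, g$between_subject_sd))
        })
        sched <- rest_work_schedule(
          cohort$work_duration, work_level = level,
          rest_fraction = g$rest_fraction,
          rest_bout = if (is.null(cohort$rest_bout)) 1 else cohort$rest_bout)
        sim <- simulate_recording(config, sched, seed = seed_k,
                                  subject_id = sid, group = gname,
                                  muscle = mname)
        cal <- simulate_calibration(config, seed = child_seed(seed_k, 11L),
                                    subject_id = sid, muscle = mname)
        stem <- sprintf("%s_%s", sid, mname)
        work_f <- paste0(stem, "_work.csv")
        base_f <- paste0(stem, "_baseline.csv")
        trial_f <- sprintf("%s_fmvc%d.csv", stem,
                           seq_along(cal$fmvc_trials))
        write_recording(sim$recording, file.path(out_dir, work_f))
        write_recording(cal$baseline, file.path(out_dir, base_f))
        for (j in seq_along(trial_f))
          write_recording(cal$fmvc_trials[[j]],
                          file.path(out_dir, trial_f[j]))
        entries[[k]] <- data.frame(
          subject_id = sid, group = gname, muscle = mname,
          work = work_f, baseline = base_f,
          fmvc_trials = I(list(trial_f)), stringsAsFactors = FALSE)
        gt <- sim$ground_truth
        truth_rows[[k]] <- data.frame(
          group = gname, subject = sid, muscle = mname,
          true_level = level, true_group_level = g$muscle_levels[[mi]],
          true_mean_envelope = gt$mean_envelope,
          true_p50 = gt$apdf[["p50"]],
          true_rest_percent = gt$rest_fraction_percent,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- cohort_manifest(do.call(rbind, entries),
                              sampling_rate = config$sampling_rate,
                              metadata = list(simulated = TRUE,
                                              seed = config$seed),
                              root = out_dir)
  mpath <- file.path(out_dir, "manifest.yaml")
  write_manifest(manifest, mpath)
  truth_matrix <- do.call(rbind, lapply(cohort$groups, function(g)
    g$muscle_levels))
  rownames(truth_matrix) <- names(cohort$groups)
  list(manifest = manifest, manifest_path = mpath,
       subject_truth = do.call(rbind, truth_rows),
       truth_matrix = truth_matrix)
}

#' Simulate a long metric dataset (metric-level generator)
#'
#' Draws per-subject metric values directly from the random-block model
#' `value = group:muscle cell mean + subject intercept + noise`, skipping
#' signal synthesis. This is the fast generator used for Monte-Carlo
#' calibration of the ANOVA (type-I error, power).
#'
#' @param n_subjects Subjects per group.
#' @param cell_means Matrix (groups x muscles) of cell means; row and
#'   column names become the group and muscle labels. Default: two groups
#'   by five muscles, all zero.
#' @param subject_sd Between-subject (block) SD (default 1).
#' @param resid_sd Residual SD (default 1).
#' @param metric Metric label stamped on the rows.
#' @param seed Optional seed.
#' @return Long data frame: group, subject, muscle, metric, value.
#' @export
simulate_metric_dataset <- function(n_subjects = 20,
                                    cell_means = matrix(
                                      0, 2, 5,
                                      dimnames = list(
                                        c("large_herd_US", "small_herd_IT"),
                                        .semg_muscles)),
                                    subject_sd = 1, resid_sd = 1,
                                    metric = "mean_rms", seed = NULL) {
  gen <- function() {
    groups <- rownames(cell_means); muscles <- colnames(cell_means)
    rows <- list(); i <- 0L
    for (g in groups) {
      for (s in seq_len(n_subjects)) {
        i <- i + 1L
        b <- rnorm(1, 0, subject_sd)
        rows[[i]] <- data.frame(
          group = g, subject = sprintf("%s_S%02d", g, s), muscle = muscles,
          metric = metric,
          value = cell_means[g, ] + b + rnorm(length(muscles), 0, resid_sd),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}
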