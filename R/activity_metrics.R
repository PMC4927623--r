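# Activity metrics: moving-window RMS envelope, mean RMS, APDF
# percentiles, percent muscular rest, and exposure-limit classification.

#' RMS envelope container
#'
#' A sliding-window root-mean-square amplitude estimate of an sEMG signal
#' on a regular time grid: one value per `step_duration` seconds, each
#' computed over a `window_duration`-second window.
#'
#' @param values Non-negative envelope values (instrument units or %fMVC).
#' @param step_duration Step between consecutive windows, seconds.
#' @param window_duration Window length, seconds.
#' @param unit `"instrument"` or `"%fMVC"`.
#' @return An object of class `rms_envelope`.
#' @export
rms_envelope <- function(values, step_duration, window_duration,
                         unit = "instrument") {
  values <- as.numeric(values)
  if (!length(values))
    semg_stop("envelope has no values", "semg_empty_input")
  if (!all(is.finite(values)) || any(values < 0))
    semg_stop("envelope values must be finite and non-negative",
              "semg_invalid_samples")
  if (step_duration <= 0 || window_duration <= 0)
    semg_stop("durations must be positive", "semg_invalid_argument")
  structure(
    list(values = values, step_duration = step_duration,
         window_duration = window_duration,
         envelope_rate = 1 / step_duration, unit = unit),
    class = "rms_envelope"
  )
}

#' @export
print.rms_envelope <- function(x, ...) {
  cat(sprintf(
    "<%s> %d values [%s], window %g s, step %g s (%.2f s covered)\n",
    class(x)[1L], length(x$values), x$unit, x$window_duration,
    x$step_duration, length(x$values) * x$step_duration))
  invisible(x)
}

#' Moving-window RMS envelope of a recording
#'
#' Standard RMS processing: the k-th envelope value (k = 0, 1, ...) is
#' `sqrt(mean(x^2))` over the samples in `[k*S, k*S + W)` where `W` and
#' `S` are the window and step in samples. The trailing partial window is
#' discarded, giving `floor((N - W)/S) + 1` values.
#'
#' Defaults (0.1 s window, 0.05 s step) are conventional for occupational
#' sEMG and resolve the 0.25-s rest-gap criterion with five envelope
#' points per minimum gap.
#'
#' @param rec An [emg_recording()].
#' @param window_duration Window length in seconds.
#' @param step_duration Step in seconds, `0 < step <= window`.
#' @return An [rms_envelope()] in the recording's units.
#' @export
compute_rms_envelope <- function(rec, window_duration = 0.1,
                                 step_duration = 0.05) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$sampling_rate
  w <- round(window_duration * fs)
  s <- round(step_duration * fs)
  if (w < 1L || s < 1L || s > w)
    semg_stop("need 0 < step_duration <= window_duration (>= one sample)",
              "semg_invalid_argument")
  n <- length(rec$samples)
  if (n < w)
    semg_stop(sprintf(
      "recording of %.3f s is shorter than one %.3f s window",
      recording_duration(rec), window_duration),
      "semg_insufficient_duration")
  k <- (n - w) %/% s + 1L
  cs <- cumsum(c(0, rec$samples^2))
  starts <- (seq_len(k) - 1L) * s
  vals <- sqrt((cs[starts + w + 1L] - cs[starts + 1L]) / w)
  rms_envelope(vals, step_duration = step_duration,
               window_duration = window_duration)
}

#' Mean of an envelope
#'
#' @param envelope An [rms_envelope()] (typically normalized to %fMVC).
#' @return Arithmetic mean of the envelope values.
#' @export
mean_rms <- function(envelope) {
  stopifnot(inherits(envelope, "rms_envelope"))
  mean(envelope$values)
}

#' Amplitude probability distribution function percentiles
#'
#' Empirical quantiles of the envelope's amplitude distribution with
#' linear interpolation between closest order statistics
#' (`stats::quantile` type 7), the conventional APDF summary: the 10th,
#' 50th and 90th percentiles describe static, median and peak load.
#'
#' @param envelope An [rms_envelope()].
#' @param percentiles Probabilities strictly inside (0, 1).
#' @return Named numeric vector (`p10`, `p50`, ... by percent level),
#'   monotone non-decreasing in the probability.
#' @export
compute_apdf <- function(envelope, percentiles = c(0.10, 0.50, 0.90)) {
  stopifnot(inherits(envelope, "rms_envelope"))
  if (!length(percentiles) || any(percentiles <= 0 | percentiles >= 1))
    semg_stop("percentiles must lie strictly inside (0, 1)",
              "semg_invalid_argument")
  q <- unname(stats::quantile(envelope$values, probs = percentiles,
                              type = 7, names = FALSE))
  names(q) <- paste0("p", formatC(100 * percentiles, format = "g"))
  q
}

#' Percent muscular rest (gap analysis)
#'
#' Share of recording time spent in rest gaps: maximal runs of
#' consecutive envelope values at or below `amplitude_threshold` whose
#' span (run length times the envelope step) is at least
#' `min_gap_duration`. The conventional criteria are a 0.5 %fMVC maximum
#' threshold and a 0.25-s minimum gap. Gap spans are measured in whole
#' envelope steps; run boundaries are not interpolated, so each edge is
#' resolved to one step.
#'
#' @param envelope A normalized [rms_envelope()] in %fMVC.
#' @param amplitude_threshold Rest threshold in %fMVC (inclusive).
#' @param min_gap_duration Minimum gap span in seconds; must not be finer
#'   than the envelope step.
#' @return Percent of recording time at rest, in `[0, 100]`.
#' @export
percent_muscular_rest <- function(envelope, amplitude_threshold = 0.5,
                                  min_gap_duration = 0.25) {
  stopifnot(inherits(envelope, "rms_envelope"))
  if (amplitude_threshold <= 0 || min_gap_duration <= 0)
    semg_stop("thresholds must be positive", "semg_invalid_argument")
  step <- envelope$step_duration
  if (min_gap_duration < step - 1e-12)
    semg_stop(sprintf(
      "minimum gap of %g s is below the envelope resolution of %g s; use a smaller step_duration",
      min_gap_duration, step), "semg_resolution_error")
  r <- rle(envelope$values <= amplitude_threshold)
  spans <- r$lengths * step
  rest <- r$values & (spans >= min_gap_duration - 1e-9)
  100 * sum(spans[rest]) / (length(envelope$values) * step)
}

#' Muscle activity profile
#'
#' The five-summary description of one normalized work recording: mean
#' RMS, APDF 10th/50th/90th percentiles, and percent muscular rest, all
#' in %fMVC (rest in percent of recording time).
#'
#' @param mean_rms,percent_rest Scalars.
#' @param apdf Named numeric vector of APDF percentiles (needs `p10`,
#'   `p50`, `p90` for exposure classification).
#' @param recording_duration Seconds of signal summarized.
#' @param params List of processing parameters (window, step, thresholds).
#' @return An object of class `muscle_activity_profile`.
#' @export
muscle_activity_profile <- function(mean_rms, apdf, percent_rest,
                                    recording_duration, params = list()) {
  if (any(c(mean_rms, apdf, percent_rest) < 0))
    semg_stop("profile metrics must be non-negative", "semg_invalid_argument")
  if (is.unsorted(apdf))
    semg_stop("APDF percentiles must be monotone non-decreasing",
              "semg_invalid_argument")
  if (percent_rest > 100)
    semg_stop("percent rest cannot exceed 100", "semg_invalid_argument")
  structure(
    list(mean_rms = mean_rms, apdf = apdf, percent_rest = percent_rest,
         recording_duration = recording_duration, params = params),
    class = "muscle_activity_profile"
  )
}

#' @export
print.muscle_activity_profile <- function(x, ...) {
  cat("<muscle_activity_profile>\n")
  cat(sprintf("  mean RMS  %8.2f %%fMVC\n", x$mean_rms))
  for (nm in names(x$apdf))
    cat(sprintf("  APDF %-4s %8.2f %%fMVC\n", nm, x$apdf[[nm]]))
  cat(sprintf("  %%MR       %8.2f %% of %.1f s\n", x$percent_rest,
              x$recording_duration))
  invisible(x)
}

#' Build the activity profile of a work recording
#'
#' Composition of the whole single-recording pipeline:
#' [compute_rms_envelope()] on the raw signal, optional baseline offset
#' subtraction (envelope minus the calibration's resting RMS, floored at
#' zero; off by default), [normalize_envelope()] to %fMVC, then
#' [mean_rms()], [compute_apdf()] and [percent_muscular_rest()].
#'
#' @param rec Work [emg_recording()].
#' @param cal A calibration result from [calibrate()] for the same
#'   subject/muscle.
#' @param window_duration,step_duration Envelope parameters, seconds.
#' @param rest_threshold %fMVC rest threshold (default 0.5).
#' @param min_gap_duration Minimum rest-gap span, seconds (default 0.25).
#' @param percentiles APDF probabilities (default 0.1, 0.5, 0.9).
#' @param subtract_baseline Subtract the resting baseline RMS from the
#'   envelope before normalizing (floored at zero)? Default `FALSE`.
#' @return A [muscle_activity_profile()].
#' @export
build_profile <- function(rec, cal, window_duration = 0.1,
                          step_duration = 0.05, rest_threshold = 0.5,
                          min_gap_duration = 0.25,
                          percentiles = c(0.10, 0.50, 0.90),
                          subtract_baseline = FALSE) {
  env <- compute_rms_envelope(rec, window_duration, step_duration)
  if (isTRUE(subtract_baseline)) {
    env$values <- pmax(env$values - cal$baseline_rms, 0)
  }
  nenv <- normalize_envelope(env, cal)
  muscle_activity_profile(
    mean_rms = mean_rms(nenv),
    apdf = compute_apdf(nenv, percentiles),
    percent_rest = percent_muscular_rest(nenv, rest_threshold,
                                         min_gap_duration),
    recording_duration = recording_duration(rec),
    params = list(window_duration = window_duration,
                  step_duration = step_duration,
                  rest_threshold = rest_threshold,
                  min_gap_duration = min_gap_duration,
                  percentiles = percentiles,
                  subtract_baseline = subtract_baseline)
  )
}

# Long-format rows (one per metric) for a profile.
profile_to_rows <- function(profile, subject_id, group, muscle) {
  data.frame(
    group = group, subject = subject_id, muscle = muscle,
    metric = .semg_metrics,
    value = c(profile$mean_rms,
              profile$apdf[["p10"]], profile$apdf[["p50"]],
              profile$apdf[["p90"]], profile$percent_rest),
    stringsAsFactors = FALSE
  )
}

#' Published exposure limit values
#'
#' Upper limit values for sustained occupational muscle load (task
#' durations of one hour or more): static load (APDF 10th percentile)
#' should not exceed 2 %MVC and must not exceed 5 %MVC; median load (50th
#' percentile) 10 and 14 %MVC; peak load (90th percentile) 50 and
#' 70 %MVC.
#'
#' @return Data frame with columns `load`, `percentile`, `should_not`,
#'   `must_not`.
#' @export
exposure_limits <- function() {
  data.frame(
    load = c("static", "median", "peak"),
    percentile = c("p10", "p50", "p90"),
    should_not = c(2, 10, 50),
    must_not = c(5, 14, 70),
    stringsAsFactors = FALSE
  )
}

#' Classify a profile against exposure limit values
#'
#' Compares the APDF 10th/50th/90th percentiles of a profile with the
#' published static/median/peak load limits ([exposure_limits()]).
#' "Exceed" means strictly greater than the limit, so a value exactly at
#' a limit is still permissible.
#'
#' @param profile A [muscle_activity_profile()], or a named numeric
#'   vector supplying `p10`, `p50`, `p90` in %fMVC.
#' @return An object of class `exposure_assessment`: a data frame with
#'   one row per load class and a `flag` column in
#'   `{within, exceeds_should_not, exceeds_must_not}`.
#' @export
classify_exposure <- function(profile) {
  apdf <- if (inherits(profile, "muscle_activity_profile")) profile$apdf
          else profile
  lim <- exposure_limits()
  missing_p <- setdiff(lim$percentile, names(apdf))
  if (length(missing_p))
    semg_stop(sprintf("profile lacks percentile(s): %s",
                      paste(missing_p, collapse = ", ")),
              "semg_invalid_argument")
  v <- as.numeric(apdf[lim$percentile])
  flag <- ifelse(v > lim$must_not, "exceeds_must_not",
                 ifelse(v > lim$should_not, "exceeds_should_not", "within"))
  out <- cbind(lim, value = v, flag = flag)
  class(out) <- c("exposure_assessment", "data.frame")
  out
}

#' @export
print.exposure_assessment <- function(x, ...) {
  cat("<exposure_assessment>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
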