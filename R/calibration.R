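# Calibration: per subject/muscle, derive the fMVC normalization constant
# from the middle-3-s RMS of maximal-effort trials, record the resting
# baseline level, and express work envelopes in %fMVC.

#' Calibration set for one subject/muscle
#'
#' Bundles the 30-s baseline rest recording and the maximal-effort (fMVC)
#' trial recordings that calibrate a work recording.
#'
#' @param baseline An [emg_recording()] with `session_kind = "baseline"`
#'   (intended duration at least 30 s; shorter baselines are accepted).
#' @param fmvc_trials List of [emg_recording()]s with
#'   `session_kind = "fmvc_trial"`.
#' @param subject_id,muscle Labels; default to the baseline's.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(baseline, fmvc_trials,
                            subject_id = baseline$subject_id,
                            muscle = baseline$muscle) {
  stopifnot(inherits(baseline, "emg_recording"))
  if (!is.list(fmvc_trials) || !length(fmvc_trials))
    semg_stop("calibration needs at least one fMVC trial",
              "semg_invalid_argument")
  for (tr in fmvc_trials) {
    stopifnot(inherits(tr, "emg_recording"))
    if (tr$sampling_rate != baseline$sampling_rate)
      semg_stop("fMVC trials and baseline must share one sampling rate",
                "semg_invalid_argument")
  }
  structure(
    list(subject_id = subject_id, muscle = muscle, baseline = baseline,
         fmvc_trials = fmvc_trials),
    class = "calibration_set"
  )
}

#' RMS over the centered window of a recording
#'
#' Root-mean-square amplitude over the middle `window_duration` seconds of
#' the recording: with `N` total samples and `W` window samples, the
#' window starts at sample offset `floor((N - W) / 2)`.
#'
#' @param rec An [emg_recording()].
#' @param window_duration Window length in seconds (default 3, the
#'   conventional scoring window of an fMVC trial).
#' @return RMS amplitude (instrument units).
#' @export
middle_window_rms <- function(rec, window_duration = 3) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(window_duration) || window_duration <= 0)
    semg_stop("window_duration must be positive", "semg_invalid_argument")
  n <- length(rec$samples)
  w <- round(window_duration * rec$sampling_rate)
  if (w > n)
    semg_stop(sprintf(
      "recording of %.3f s is shorter than the %.3f s scoring window",
      recording_duration(rec), window_duration),
      "semg_insufficient_duration")
  start <- floor((n - w) / 2) + 1L
  x <- rec$samples[start:(start + w - 1L)]
  sqrt(mean(x^2))
}

#' Derive the fMVC calibration for one subject/muscle
#'
#' Scores each maximal-effort trial by the RMS of its middle
#' `window_duration` seconds and takes the maximum across trials as the
#' fMVC normalization denominator (`trial_statistic = "mean"` averages
#' instead). The baseline resting RMS is computed over the entire baseline
#' recording and reported alongside; it is not subtracted from work
#' signals unless requested downstream.
#'
#' Fewer than three trials triggers a warning (class
#' `semg_few_trials_warning`), mirroring the usual at-least-three-trials
#' protocol, but never an error.
#'
#' @param cal A [calibration_set()].
#' @param window_duration Scoring window in seconds (default 3).
#' @param trial_statistic `"max"` (default, MVC convention) or `"mean"`.
#' @return An object of class `calibration_result` with fields
#'   `fmvc_value`, `per_trial_values`, `baseline_rms`, `trial_count`.
#' @export
calibrate <- function(cal, window_duration = 3,
                      trial_statistic = c("max", "mean")) {
  stopifnot(inherits(cal, "calibration_set"))
  trial_statistic <- match.arg(trial_statistic)
  per_trial <- vapply(cal$fmvc_trials, middle_window_rms, numeric(1),
                      window_duration = window_duration)
  if (length(per_trial) < 3L)
    semg_warn(sprintf(
      "subject %s / %s: only %d fMVC trial(s); at least 3 are recommended",
      cal$subject_id, cal$muscle, length(per_trial)),
      "semg_few_trials_warning")
  fmvc <- if (trial_statistic == "max") max(per_trial) else mean(per_trial)
  if (fmvc <= 0)
    semg_stop(sprintf(
      "subject %s / %s: all fMVC trials are zero; normalization impossible",
      cal$subject_id, cal$muscle), "semg_degenerate_calibration")
  baseline_rms <- sqrt(mean(cal$baseline$samples^2))
  structure(
    list(fmvc_value = fmvc, per_trial_values = per_trial,
         baseline_rms = baseline_rms, trial_count = length(per_trial),
         window_duration = window_duration,
         trial_statistic = trial_statistic,
         subject_id = cal$subject_id, muscle = cal$muscle),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s / %s\n", x$subject_id, x$muscle))
  cat(sprintf("  fMVC = %.6g (%s of %d trials: %s)\n", x$fmvc_value,
              x$trial_statistic, x$trial_count,
              paste(signif(x$per_trial_values, 4), collapse = ", ")))
  cat(sprintf("  baseline RMS = %.6g\n", x$baseline_rms))
  invisible(x)
}

#' Normalize an RMS envelope to %fMVC
#'
#' Each envelope value `v` becomes `100 * v / fmvc_value`; the time grid
#' is unchanged. Because both the envelope and the calibration are in the
#' same instrument units, the result is scale-invariant.
#'
#' @param envelope An [rms_envelope()] in instrument units.
#' @param cal A calibration result from [calibrate()].
#' @return A `normalized_envelope` (an [rms_envelope()] whose values are
#'   in %fMVC).
#' @export
normalize_envelope <- function(envelope, cal) {
  stopifnot(inherits(envelope, "rms_envelope"),
            inherits(cal, "calibration_result"))
  if (!is.finite(cal$fmvc_value) || cal$fmvc_value <= 0)
    semg_stop("fMVC value must be positive to normalize",
              "semg_degenerate_calibration")
  out <- envelope
  out$values <- 100 * envelope$values / cal$fmvc_value
  out$unit <- "%fMVC"
  class(out) <- unique(c("normalized_envelope", class(envelope)))
  out
}

#' Band-pass pre-filter (optional stage, off by default)
#'
#' Zero-phase Butterworth band-pass of the raw signal. The default
#' pipeline applies no filtering, so profiles are reproducible from the
#' normalization and envelope steps alone; enable this stage explicitly
#' when the instrument exports unfiltered wide-band data.
#'
#' @param rec An [emg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth order (default 4).
#' @return A filtered [emg_recording()].
#' @export
bandpass_filter <- function(rec, low = 20, high = 450, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    semg_stop(sprintf(
      "band edges must satisfy 0 < low < high < %g Hz (Nyquist)", nyq),
      "semg_invalid_argument")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}
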