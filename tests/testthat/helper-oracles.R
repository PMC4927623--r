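# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation: explicit loops over
# windows, full-sort quantiles, and explicit run enumeration.

# Moving-window RMS by looping over windows.
oracle_envelope <- function(x, fs, window_duration, step_duration) {
  w <- round(window_duration * fs)
  s <- round(step_duration * fs)
  k <- floor((length(x) - w) / s) + 1
  out <- numeric(k)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * s + 1):((i - 1) * s + w)]
    out[i] <- sqrt(sum(seg^2) / w)
  }
  out
}

# Quantile with linear interpolation between closest order statistics,
# from first principles: h = (n - 1) p + 1.
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }, numeric(1))
}

# Percent rest by explicit enumeration of all runs.
oracle_pmr <- function(values, step, threshold, min_gap) {
  n <- length(values)
  rest_time <- 0
  i <- 1
  while (i <= n) {
    if (values[i] <= threshold) {
      j <- i
      while (j < n && values[j + 1] <= threshold) j <- j + 1
      span <- (j - i + 1) * step
      if (span >= min_gap - 1e-9) rest_time <- rest_time + span
      i <- j + 1
    } else i <- i + 1
  }
  100 * rest_time / (n * step)
}

# Streaming (Welford) mean/SD oracle.
oracle_mean_sd <- function(v) {
  m <- 0; s <- 0; n <- 0
  for (x in v) {
    n <- n + 1
    d <- x - m
    m <- m + d / n
    s <- s + d * (x - m)
  }
  c(mean = m, sd = if (n > 1) sqrt(s / (n - 1)) else NA_real_)
}

# Constant-amplitude recording.
const_recording <- function(value, duration, fs = 1000, ...) {
  emg_recording(rep(value, round(duration * fs)), sampling_rate = fs, ...)
}

# Calibration result from constant trials (value = fMVC) and a quiet
# baseline, without warnings.
const_calibration <- function(fmvc = 1, fs = 1000) {
  cal <- calibration_set(
    const_recording(0.001, 30, fs, session_kind = "baseline"),
    lapply(c(0.6, 0.8, 1) * fmvc, function(v)
      const_recording(v, 5, fs, session_kind = "fmvc_trial"))
  )
  calibrate(cal)
}

# Normalized envelope straight from values (unit %fMVC).
values_envelope <- function(values, step = 0.05, window = 0.1) {
  env <- rms_envelope(values, step_duration = step, window_duration = window,
                      unit = "%fMVC")
  class(env) <- c("normalized_envelope", class(env))
  env
}

# Small simulation config for fast tests: 400 Hz, 20-150 Hz band.
fast_config <- function(seed, ...) {
  simulation_config(seed = seed, sampling_rate = 400,
                    noise_band = c(20, 150), ...)
}

# Tiny cohort block (2 groups x 3 subjects x 3 muscles, short recordings).
tiny_cohort <- function(work_duration = 15) {
  list(
    work_duration = work_duration,
    rest_bout = 1,
    groups = list(
      large_herd_US = list(
        n_subjects = 3,
        muscle_levels = c(upper_trapezius = 14, biceps_brachii = 19,
                          wrist_flexors = 12),
        between_subject_sd = 2, rest_fraction = 0.2),
      small_herd_IT = list(
        n_subjects = 3,
        muscle_levels = c(upper_trapezius = 8, biceps_brachii = 7,
                          wrist_flexors = 6),
        between_subject_sd = 2, rest_fraction = 0.1)
    )
  )
}
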