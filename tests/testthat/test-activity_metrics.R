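test_that("envelope of a constant signal is that constant", {
  env <- compute_rms_envelope(const_recording(2, 1))
  expect_true(all(abs(env$values - 2) < 1e-12))
  expect_length(env$values, (1000 - 100) %/% 50 + 1)
})

test_that("envelope of a sinusoid is A/sqrt(2) when windows hold whole periods", {
  a <- 1.4
  t <- (1:2000) / 1000
  rec <- emg_recording(a * sin(2 * pi * 20 * t), 1000)  # 0.1 s = 2 periods
  env <- compute_rms_envelope(rec, 0.1, 0.05)
  expect_lt(max(abs(env$values - a / sqrt(2))), 1e-3 * a)
})

test_that("envelope matches the brute-force oracle exactly", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(1000)
    env <- compute_rms_envelope(emg_recording(x, 1000), 0.1, 0.05)
    expect_equal(env$values, oracle_envelope(x, 1000, 0.1, 0.05),
                 tolerance = 1e-12)
  }
  # uneven window/step combination
  x <- rnorm(777)
  env <- compute_rms_envelope(emg_recording(x, 1000), 0.083, 0.031)
  expect_equal(env$values, oracle_envelope(x, 1000, 0.083, 0.031),
               tolerance = 1e-12)
})

test_that("envelope count invariant and error contracts hold", {
  for (n in c(150, 1000, 1234)) {
    env <- compute_rms_envelope(emg_recording(rnorm(n), 1000), 0.1, 0.05)
    expect_length(env$values, (n - 100) %/% 50 + 1)
  }
  expect_error(compute_rms_envelope(const_recording(1, 0.05), 0.1),
               class = "semg_insufficient_duration")
  expect_error(compute_rms_envelope(const_recording(1, 1), 0.05, 0.1),
               class = "semg_invalid_argument")
})

test_that("metrics are invariant to sign flips of the raw signal", {
  set.seed(3)
  x <- rnorm(2000)
  e1 <- compute_rms_envelope(emg_recording(x, 1000))
  e2 <- compute_rms_envelope(emg_recording(-x, 1000))
  expect_identical(e1$values, e2$values)
})

test_that("mean RMS is the arithmetic mean of the envelope", {
  expect_equal(mean_rms(values_envelope(rep(7, 40))), 7)
  expect_equal(mean_rms(values_envelope(c(rep(0, 20), rep(10, 20)))), 5)
  expect_error(rms_envelope(numeric(0), 0.05, 0.1),
               class = "semg_empty_input")
})

test_that("APDF percentiles use linear interpolation and stay monotone", {
  expect_equal(unname(compute_apdf(values_envelope(rep(3.3, 25)))),
               rep(3.3, 3))
  expect_equal(compute_apdf(values_envelope(1:99))[["p50"]], 50)
  set.seed(8)
  v <- rexp(10000) * 10
  q <- compute_apdf(values_envelope(v), c(0.1, 0.5, 0.9))
  expect_equal(unname(q), oracle_quantile(v, c(0.1, 0.5, 0.9)),
               tolerance = 1e-12)
  expect_true(all(diff(q) >= 0))
  expect_error(compute_apdf(values_envelope(1:10), c(0, 0.5)),
               class = "semg_invalid_argument")
})

test_that("percent rest follows the threshold and minimum-gap rules", {
  expect_equal(percent_muscular_rest(values_envelope(rep(0, 100))), 100)
  expect_equal(percent_muscular_rest(values_envelope(rep(10, 100))), 0)
  # a 0.20-s sub-threshold run (4 values at 0.05-s steps) is below the
  # 0.25-s minimum gap and does not count
  v <- c(rep(10, 50), rep(0.2, 4), rep(10, 50))
  expect_equal(percent_muscular_rest(values_envelope(v)), 0)
  # one more value crosses the minimum gap
  v5 <- c(rep(10, 50), rep(0.2, 5), rep(10, 50))
  expect_equal(percent_muscular_rest(values_envelope(v5)),
               100 * 5 / 105)
  # the threshold is inclusive: exactly 0.5 %fMVC counts as rest
  expect_equal(percent_muscular_rest(values_envelope(rep(0.5, 100))), 100)
  expect_error(percent_muscular_rest(values_envelope(rep(0, 10)),
                                     min_gap_duration = 0.01),
               class = "semg_resolution_error")
})

test_that("percent rest equals brute-force run enumeration on random envelopes", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(50:1000, 1)
    v <- abs(rnorm(n, mean = 0.6, sd = 0.5))
    got <- percent_muscular_rest(values_envelope(v), 0.5, 0.25)
    expect_equal(got, oracle_pmr(v, 0.05, 0.5, 0.25), tolerance = 1e-12)
  }
})

test_that("percent rest is monotone in its two parameters", {
  set.seed(13)
  for (i in 1:10) {
    v <- abs(rnorm(400, 0.5, 0.4))
    env <- values_envelope(v)
    thr <- c(0.2, 0.5, 1, 2)
    by_thr <- vapply(thr, function(a)
      percent_muscular_rest(env, a, 0.25), numeric(1))
    expect_true(all(diff(by_thr) >= 0))        # non-decreasing in threshold
    gaps <- c(0.05, 0.25, 0.5, 1)
    by_gap <- vapply(gaps, function(g)
      percent_muscular_rest(env, 0.5, g), numeric(1))
    expect_true(all(diff(by_gap) <= 0))        # non-increasing in min gap
  }
})

test_that("profiles hit the analytic corner cases", {
  cal <- const_calibration(fmvc = 2)
  at_fmvc <- build_profile(const_recording(2, 10), cal)
  expect_equal(at_fmvc$mean_rms, 100)
  expect_equal(unname(at_fmvc$apdf), rep(100, 3))
  expect_equal(at_fmvc$percent_rest, 0)

  silent <- build_profile(const_recording(0, 10), cal)
  expect_equal(silent$mean_rms, 0)
  expect_equal(unname(silent$apdf), rep(0, 3))
  expect_equal(silent$percent_rest, 100)
})

test_that("profile invariants hold on simulated recordings", {
  cfg <- fast_config(seed = 9)
  sch <- rest_work_schedule(20, work_level = 25, rest_fraction = 0.3)
  sim <- simulate_recording(cfg, sch, seed = 9)
  cal <- calibrate(simulate_calibration(cfg, seed = 10,
                                        baseline_duration = 10))
  prof <- build_profile(sim$recording, cal)
  expect_true(prof$apdf[["p10"]] <= prof$apdf[["p50"]])
  expect_true(prof$apdf[["p50"]] <= prof$apdf[["p90"]])
  expect_true(prof$percent_rest >= 0 && prof$percent_rest <= 100)
  expect_equal(prof$recording_duration, 20)
})

test_that("exposure classification applies strict limits per load class", {
  # published profile values: median load above both limits,
  # peak above the should-not limit only
  cls <- classify_exposure(c(p10 = 1.21, p50 = 14.58, p90 = 51.22))
  expect_identical(cls$flag[cls$load == "median"], "exceeds_must_not")
  expect_identical(cls$flag[cls$load == "peak"], "exceeds_should_not")
  expect_identical(cls$flag[cls$load == "static"], "within")

  within_all <- classify_exposure(c(p10 = 0, p50 = 10, p90 = 50))
  expect_identical(within_all$flag, rep("within", 3))  # limits are permissible

  must <- classify_exposure(c(p10 = 5.01, p50 = 14.01, p90 = 70.01))
  expect_identical(must$flag, rep("exceeds_must_not", 3))
  expect_error(classify_exposure(c(p10 = 1, p50 = 2)),
               class = "semg_invalid_argument")
})
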