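test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- fast_config(seed = 12)
  sch <- task_schedule(c("a", "b"), c(2, 2), c(20, 40))
  r1 <- simulate_recording(cfg, sch, seed = 12)$recording
  r2 <- simulate_recording(cfg, sch, seed = 12)$recording
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_recording(cfg, sch, seed = 13)$recording
  expect_false(identical(r1$samples, r3$samples))
})

test_that("segment RMS is exact by construction and zero segments are silent", {
  cfg <- fast_config(seed = 3, mvc_reference_amplitude = 2)
  sch <- task_schedule(c("w1", "off", "w2"), c(2, 1, 3), c(25, 0, 60))
  rec <- simulate_recording(cfg, sch, seed = 3)$recording
  fs <- rec$sampling_rate
  seg <- function(from, to) rec$samples[(from * fs + 1):(to * fs)]
  expect_equal(sqrt(mean(seg(0, 2)^2)), 0.25 * 2, tolerance = 1e-12)
  expect_identical(unique(seg(2, 3)), 0)
  expect_equal(sqrt(mean(seg(3, 6)^2)), 0.60 * 2, tolerance = 1e-12)
  expect_equal(mean(rec$samples), 0, tolerance = 0.05)
})

test_that("schedule ground truth is analytic: mean, APDF, rest fraction", {
  s2 <- task_schedule(c("a", "b"), c(5, 5), c(20, 40))
  gt <- schedule_ground_truth(s2)
  expect_equal(gt$mean_envelope, 30)
  expect_equal(gt$apdf[["p50"]], 30)  # midpoint convention on the boundary
  expect_equal(gt$apdf[["p10"]], 20)
  expect_equal(gt$apdf[["p90"]], 40)
  expect_equal(gt$rest_fraction_percent, 0)

  # adjacent sub-threshold segments merge into one bout; short bouts are
  # excluded by the same minimum-gap rule the %MR metric uses
  s3 <- task_schedule(c("r1", "r2", "w", "blip", "w2"),
                      c(0.2, 0.3, 2, 0.2, 1),
                      c(0.1, 0.4, 20, 0.2, 20))
  gt3 <- schedule_ground_truth(s3)
  expect_equal(gt3$rest_fraction_percent, 100 * 0.5 / 3.7, tolerance = 1e-12)

  single <- schedule_ground_truth(task_schedule("only", 4, 12))
  expect_equal(unname(single$apdf), rep(12, 3))
})

test_that("rest/work schedules tile the requested duration and fraction", {
  sch <- rest_work_schedule(60, work_level = 20, rest_fraction = 0.3,
                            rest_bout = 1)
  expect_equal(sum(sch$duration), 60)
  gt <- schedule_ground_truth(sch)
  expect_equal(gt$rest_fraction_percent, 30, tolerance = 0.5)
  expect_error(rest_work_schedule(60, 20, rest_fraction = 1.2),
               class = "semg_invalid_argument")
})

test_that("the canonical milking cycle has 30% rest and interior median", {
  sch <- milking_schedule(60)
  expect_equal(sum(sch$duration), 600)
  gt <- schedule_ground_truth(sch)
  expect_equal(gt$rest_fraction_percent, 30)
  expect_equal(gt$apdf[["p50"]], 15)
  expect_equal(gt$apdf[["p90"]], 35)
})

test_that("simulated calibration mirrors the field protocol", {
  cfg <- simulation_config(seed = 8)
  cs <- simulate_calibration(cfg)
  expect_length(cs$fmvc_trials, 3L)
  expect_true(all(vapply(cs$fmvc_trials, recording_duration,
                         numeric(1)) >= 5))
  expect_gte(recording_duration(cs$baseline), 30)
  cal <- calibrate(cs)
  expect_equal(cal$fmvc_value, cfg$mvc_reference_amplitude,
               tolerance = 0.05)
})

test_that("normalizing a maximal work segment recovers ~100 %fMVC", {
  cfg <- simulation_config(seed = 19)
  sim <- simulate_recording(cfg, task_schedule("max", 10, 100), seed = 19)
  cal <- calibrate(simulate_calibration(cfg, seed = 20))
  prof <- build_profile(sim$recording, cal)
  expect_equal(prof$mean_rms, 100, tolerance = 0.07)
})

test_that("config validation rejects Nyquist-violating noise bands", {
  expect_error(simulation_config(seed = 1, sampling_rate = 500,
                                 noise_band = c(20, 450)),
               class = "semg_invalid_argument")
  expect_error(simulation_config(seed = 1, noise_band = c(-5, 100)),
               class = "semg_invalid_argument")
  expect_error(simulation_config(seed = 1, mvc_reference_amplitude = 0),
               class = "semg_invalid_argument")
})

test_that("simulated cohorts write a readable, truthful file inventory", {
  cfg <- fast_config(seed = 77, cohort = tiny_cohort())
  out <- withr::local_tempdir()
  sim <- simulate_command(cfg, out)
  expect_true(file.exists(sim$manifest_path))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  m <- read_manifest(sim$manifest_path)
  expect_equal(nrow(m$entries), 2 * 3 * 3)
  expect_equal(nrow(sim$subject_truth), 18L)
  expect_equal(dim(sim$truth_matrix), c(2L, 3L))
  # every referenced file exists and parses
  rec <- read_recording(file.path(out, m$entries$work[1]),
                        sampling_rate = m$sampling_rate)
  expect_equal(recording_duration(rec), 15)
  # same seed regenerates identical signals; different seed differs but
  # keeps the same inventory
  out2 <- withr::local_tempdir()
  simulate_command(cfg, out2)
  f <- m$entries$work[1]
  expect_identical(readLines(file.path(out, f)),
                   readLines(file.path(out2, f)))
  out3 <- withr::local_tempdir()
  cfg3 <- fast_config(seed = 78, cohort = tiny_cohort())
  sim3 <- simulate_command(cfg3, out3)
  expect_identical(sort(list.files(out3)), sort(list.files(out2)))
  expect_false(identical(readLines(file.path(out3, f)),
                         readLines(file.path(out2, f))))
})

test_that("cohort cell means are recoverable when subject spread is zero", {
  blk <- tiny_cohort()
  blk$groups$large_herd_US$between_subject_sd <- 0
  blk$groups$small_herd_IT$between_subject_sd <- 0
  blk$groups$large_herd_US$n_subjects <- 2
  blk$groups$small_herd_IT$n_subjects <- 2
  cfg <- fast_config(seed = 55, cohort = blk)
  out <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, out)
  rep <- suppressWarnings(suppressMessages(
    run_pipeline(list(manifest = sim$manifest_path),
                 out_dir = file.path(out, "res"), metric = "mean_rms")))
  s <- rep$summaries$mean_rms
  for (i in seq_len(nrow(s))) {
    truth <- sim$truth_matrix[s$group[i], s$muscle[i]]
    rest <- blk$groups[[s$group[i]]]$rest_fraction
    # duration-weighted mean envelope: rest bouts sit at 0.2 %MVC
    expected <- truth * (1 - rest) + 0.2 * rest
    expect_equal(s$mean[i], expected, tolerance = 0.05 * expected)
  }
})
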