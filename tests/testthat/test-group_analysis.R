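test_that("group summaries use sample SD and flag single-subject cells", {
  d <- data.frame(group = "g", subject = c("a", "b"),
                  muscle = "biceps_brachii", metric = "mean_rms",
                  value = c(10, 20))
  s <- aggregate_profiles(d)
  expect_equal(s$mean, 15)
  expect_equal(s$sd, sqrt(50), tolerance = 1e-9)  # 7.0711
  expect_equal(s$n, 2L)

  same <- d; same$value <- c(4, 4)
  expect_equal(aggregate_profiles(same)$sd, 0)

  one <- d[1, ]
  s1 <- aggregate_profiles(one)
  expect_equal(s1$mean, 10)
  expect_true(is.na(s1$sd))
})

test_that("group summaries match a streaming oracle and ignore row order", {
  set.seed(41)
  d <- data.frame(group = "g", subject = sprintf("S%02d", 1:30),
                  muscle = "wrist_flexors", metric = "apdf_p50",
                  value = rlnorm(30, 2, 0.4))
  s <- aggregate_profiles(d)
  o <- oracle_mean_sd(d$value)
  expect_equal(s$mean, unname(o["mean"]), tolerance = 1e-12)
  expect_equal(s$sd, unname(o["sd"]), tolerance = 1e-12)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(aggregate_profiles(shuffled), s, ignore_attr = TRUE)
})

test_that("balanced-design estimates equal cell means and deltas their difference", {
  d <- simulate_metric_dataset(
    n_subjects = 8,
    cell_means = matrix(c(12, 6, 9, 7, 15, 5, 8, 8, 11, 4), nrow = 2,
                        dimnames = list(c("large_herd_US", "small_herd_IT"),
                                        semg_muscles())),
    subject_sd = 1, resid_sd = 1, seed = 99)
  fit <- fit_random_block_anova(d, "mean_rms")
  sme <- simple_main_effects(fit)
  cellmean <- function(g, m) mean(d$value[d$group == g & d$muscle == m])
  for (i in seq_len(nrow(sme))) {
    m <- sme$muscle[i]
    expect_equal(sme$estimate_group_a[i], cellmean("large_herd_US", m),
                 tolerance = 1e-6)
    expect_equal(sme$estimate_group_b[i], cellmean("small_herd_IT", m),
                 tolerance = 1e-6)
  }
  expect_equal(sme$delta, sme$estimate_group_a - sme$estimate_group_b,
               tolerance = 1e-9)
  expect_identical(sme$muscle, fit$muscles)
  expect_true(all(sme$p_adjusted >= sme$p_unadjusted))
  expect_true(all(sme$p_adjusted >= 0 & sme$p_adjusted <= 1))
})

test_that("ANOVA reports all fixed terms with valid statistics", {
  d <- simulate_metric_dataset(n_subjects = 10, seed = 7)
  fit <- fit_random_block_anova(d, "mean_rms")
  expect_setequal(fit$terms$term, c("group", "muscle", "group:muscle"))
  expect_true(all(fit$terms$p >= 0 & fit$terms$p <= 1))
  expect_true(all(fit$terms$df1 > 0 & fit$terms$df2 > 0))
  expect_false(interaction_significant(fit) && fit$terms$p[
    fit$terms$term == "group:muscle"] >= 0.05)
})

test_that("relabeling the groups negates deltas and keeps p-values", {
  d <- simulate_metric_dataset(n_subjects = 10, seed = 15)
  d$value[d$group == "large_herd_US" & d$muscle == "biceps_brachii"] <-
    d$value[d$group == "large_herd_US" & d$muscle == "biceps_brachii"] + 1.5
  sme1 <- simple_main_effects(fit_random_block_anova(d, "mean_rms"))
  # swap the A/B convention: the first-seen group becomes the other one
  d2 <- d[order(match(d$group, c("small_herd_IT", "large_herd_US"))), ]
  sme2 <- simple_main_effects(fit_random_block_anova(d2, "mean_rms"))
  expect_equal(sme2$delta, -sme1$delta, tolerance = 1e-8)
  expect_equal(sme2$p_unadjusted, sme1$p_unadjusted, tolerance = 1e-8)
  expect_equal(sme2$p_adjusted, sme1$p_adjusted, tolerance = 1e-3)
})

test_that("degenerate designs are refused with a diagnostic", {
  d <- simulate_metric_dataset(n_subjects = 5, seed = 2)
  const <- d; const$value <- 3
  expect_error(fit_random_block_anova(const, "mean_rms"),
               class = "semg_model_error")

  solo <- d[d$group == "small_herd_IT" | d$subject == "large_herd_US_S01", ]
  err <- expect_error(fit_random_block_anova(solo, "mean_rms"),
                      class = "semg_model_error")
  expect_match(conditionMessage(err), "large_herd_US")

  onegroup <- d[d$group == "small_herd_IT", ]
  expect_error(fit_random_block_anova(onegroup, "mean_rms"),
               class = "semg_model_error")
})

test_that("subjects with incomplete muscle data are dropped listwise", {
  d <- simulate_metric_dataset(n_subjects = 6, seed = 4)
  d <- d[!(d$subject == "large_herd_US_S01" &
             d$muscle == "biceps_brachii"), ]
  expect_message(fit <- fit_random_block_anova(d, "mean_rms"),
                 "1 subject")
  expect_equal(fit$dropped_subjects, 1L)
  expect_equal(fit$n_subjects, 11L)
})

test_that("adjusted p-values are never anti-conservative across seeds", {
  for (s in 1:12) {
    d <- simulate_metric_dataset(n_subjects = 6, seed = 100 + s)
    sme <- simple_main_effects(
      suppressWarnings(fit_random_block_anova(d, "mean_rms")))
    expect_true(all(sme$p_adjusted >= sme$p_unadjusted))
  }
})

test_that("published reference tables load with expected shape", {
  ref <- reference_tables()
  expect_equal(nrow(ref$profiles), 50L)  # 2 groups x 5 muscles x 5 metrics
  expect_setequal(unique(ref$profiles$metric), semg_metrics())
  t4 <- ref$simple_effects_mean_rms
  expect_equal(nrow(t4), 5L)
  expect_setequal(t4$muscle, semg_muscles())
})
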