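test_that("regimens expand into explicit titration schedules", {
  reg <- regimen_qd(c(2, 4), days_each = 7)
  sched <- regimen_schedule(reg)
  expect_equal(nrow(sched), 14)
  expect_equal(sched$time_h, seq(0, 312, by = 24))
  expect_equal(sched$amount_mg, rep(c(2, 4), each = 7))
  expect_error(regimen_qd(c(2, 0)))
})

test_that("repeated dosing accumulates exposure toward steady state", {
  subj <- sample_subject(population_spec("general_nec"), seed = 7,
                         age_range = c(47, 81), sex = "F")
  sched <- regimen_schedule(regimen_qd(2, days_each = 7))
  prof <- simulate_profile(subj, drug_ropinirole(), mr_weibull(),
                           dose_schedule = sched, t_end = 7 * 24)
  day <- function(d) {
    w <- prof[prof$time_h >= (d - 1) * 24 & prof$time_h <= d * 24, ]
    w$time_h <- w$time_h - (d - 1) * 24
    nca_metrics(w, dosing_interval = 24)
  }
  d1 <- day(1); d6 <- day(6); d7 <- day(7)
  expect_gt(d7$auc_0_tau, d1$auc_0_tau)
  # near steady state the daily peak drifts by less than 2%
  expect_lt(abs(d7$cmax - d6$cmax) / d6$cmax, 0.02)
  # observed accumulation is consistent with the 1/(1 - e^(-lambda_z tau))
  # superposition ratio from the terminal slope of the washout
  tail_prof <- prof[prof$time_h >= 6 * 24, ]
  expect_true(d7$lambda_z_estimable)
  r_obs <- d7$auc_0_tau / d1$auc_0_tau
  r_pred <- 1 / (1 - exp(-d7$lambda_z * 24))
  expect_lt(abs(r_obs - r_pred) / r_pred, 0.25)
})

test_that("a small virtual trial runs, summarizes and is seed-reproducible", {
  cfg <- small_trial_config(dose_mg = 8, n = 2)
  tr1 <- simulate_trial(cfg, seed = 42)
  tr2 <- simulate_trial(cfg, seed = 42)
  expect_identical(tr1$metrics, tr2$metrics)
  expect_identical(tr1$profiles, tr2$profiles)
  expect_equal(length(tr1$failures), 0)
  expect_true(all(tr1$metrics$cmax > 0))
  expect_s3_class(tidy(tr1), "tbl_df")
  expect_s3_class(autoplot(tr1), "ggplot")
  # a different seed gives a different cohort
  tr3 <- simulate_trial(cfg, seed = 43)
  expect_false(isTRUE(all.equal(tr1$metrics$cmax, tr3$metrics$cmax)))
})

test_that("population bands collapse for one subject and degenerate cohorts", {
  cfg <- small_trial_config(dose_mg = 4, n = 1)
  tr <- simulate_trial(cfg, seed = 1)
  b <- tr$summary$bands
  expect_equal(b$p5, b$mean)
  expect_equal(b$p95, b$mean)
  # identical subjects give zero-width bands
  cohort <- tr$cohort[c(1, 1), ]
  cohort$subject_id <- 1:2
  tr2 <- simulate_trial(cfg, seed = 1, cohort = cohort)
  expect_equal(tr2$summary$bands$p5, tr2$summary$bands$p95)
  # geometric mean never exceeds the arithmetic mean
  s <- tr2$summary$metrics
  expect_true(all(s$geomean <= s$mean + 1e-12))
})

test_that("fold assessment is symmetric and applies the two-fold rule", {
  sim <- tibble::tibble(metric = c("cmax", "tmax"), mean = c(10, 2.37),
                        geomean = c(9, 2.3), median = c(10, 2.4))
  obs <- tibble::tibble(metric = c("cmax", "tmax"), value = c(10, 1))
  fr <- fold_assessment(sim, obs, statistic = "mean")
  expect_equal(fr$fold[fr$metric == "cmax"], 1)
  expect_true(fr$pass[fr$metric == "cmax"])
  # the 2.37-fold case exceeds the criterion
  expect_equal(fr$fold[fr$metric == "tmax"], 2.37)
  expect_false(fr$pass[fr$metric == "tmax"])
  # symmetry: swapping simulated and observed leaves the fold unchanged
  fr_swap <- fold_assessment(tibble::tibble(metric = "cmax", mean = 10,
                                            geomean = 10, median = 10),
                             tibble::tibble(metric = "cmax", value = 25))
  expect_equal(fr_swap$fold, 2.5)
  expect_false(fr_swap$pass)
  # pass flag is exactly fold <= 2
  expect_equal(fr$pass, fr$fold <= 2)
  # zero observed values are skipped with a warning
  expect_warning(
    fr0 <- fold_assessment(sim, tibble::tibble(metric = c("cmax", "tmax"),
                                               value = c(10, 0))),
    "Skipping")
  expect_equal(nrow(fr0), 1)
})

test_that("dissolution inputs propagate monotonically into exposure", {
  cfg <- small_trial_config(dose_mg = 8, n = 2)
  slow <- mr_weibull()
  fast <- weibull_params(slow$alpha / 2, slow$beta)  # uniformly faster release
  exp_res <- run_experiment_dissolution_sensitivity(
    cfg, list(slow = slow, fast = fast), seed = 5)
  expect_true(all(exp_res$paired$cmax_ratio > 1))
  expect_true(all(exp_res$paired$tmax_diff < 0))
  # identical inputs give bitwise identical outputs
  same <- run_experiment_dissolution_sensitivity(
    cfg, list(a = slow, b = slow), seed = 5)
  expect_identical(same$results$a$metrics$cmax, same$results$b$metrics$cmax)
  expect_true(all(same$paired$cmax_ratio == 1))
})

test_that("sparse and dense samplings of one release curve predict similar exposure", {
  truth <- mr_weibull()
  t3 <- c(2, 12, 24)
  t8 <- c(0.5, 1, 2, 4, 8, 12, 18, 24)
  p3 <- gen_dissolution_points(truth, t3, cv = 0, seed = 1)
  p8 <- gen_dissolution_points(truth, t8, cv = 0, seed = 1)
  cfg <- small_trial_config(dose_mg = 8, n = 2)
  exp_res <- run_experiment_dissolution_sensitivity(
    cfg, list(three_point = p3, eight_point = p8), seed = 9)
  expect_true(all(abs(exp_res$paired$auc_ratio - 1) < 0.05))
})

test_that("geriatric age bands show increasing exposure with age", {
  cfg <- small_trial_config(dose_mg = 4, n = 3)
  cfg$population <- "geriatric_nec"
  res <- run_experiment_age_bands(cfg, list(c(65, 75), c(75, 85), c(85, 98)),
                                  seed = 2)
  expect_true(all(diff(res$by_band$mean_auc_0_tau) > 0))
  # identical bands give identical exposure
  same <- run_experiment_age_bands(cfg, list(c(70, 80), c(70, 80)), seed = 2)
  expect_identical(same$by_band$mean_auc_0_tau[1], same$by_band$mean_auc_0_tau[2])
})
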